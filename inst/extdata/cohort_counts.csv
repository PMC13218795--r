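cohort,item,value
rgqbf_embryos,total,103
rgqbf_embryos,complex_aneuploid,65
rgqbf_embryos,aneuploid,82
rgqbf_embryos,band_4_15,61
rgqbf_couples,total,50
rgqbf_couples,exclusively_complex,25
sgqbf_embryos,total,58
sgqbf_embryos,complex_aneuploid,1
sgqbf_embryos,simple_aneuploid,24
sgqbf_couples,total,30
wes_cohort,total,109
wes_cohort,homozygous_carriers,13
wes_cohort,compound_het_carriers,7
blastocysts,total,15397
blastocysts,aneuploid,3214
blastocysts,simple_aneuploid,3091
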