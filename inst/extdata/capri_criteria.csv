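class,rank,fnat_min,lrmsd_max,irmsd_max
high,3,0.5,1.0,1.0
medium,2,0.3,5.0,2.0
acceptable,1,0.1,10.0,4.0
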