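cluster,stratum,wt,age_m,bm,milk,yogurt,cereal,beans,meat,fish,egg,pumpkin,mango,hh_id
c1,s1,1.2,8,1,1,0,1,0,0,1,0,9,0,h1
c1,s1,0.8,15,0,0,1,1,1,0,0,1,1,1,h1
c2,s1,1.0,24,1,1,0,1,0,0,0,0,0,0,h9
c2,s1,1.5,6,yes,0,0,0,0,0,0,0,0,0,h2
c2,s1,0,12,1,1,0,1,1,0,0,0,0,0,h9
c3,s2,1.1,23,0,1,0,1,1,1,0,1,0,0,h3
c3,s2,0.9,4,1,1,0,0,0,0,0,0,0,0,h9
c3,s2,1.0,18,1,0,0,1,0,0,0,0,0,0,h3
c4,s2,2.0,11,1,0,1,1,0,1,0,0,1,0,h4
c4,s2,0.7,13,0,0,0,1,1,0,0,0,0,1,h5
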