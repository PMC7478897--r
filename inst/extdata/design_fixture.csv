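"child_id","cluster_id","stratum_id","weight","age_months","breastfed","grains","legumes","dairy","flesh","eggs","vita_fruit_veg","other_fruit_veg","country_label"
"c000001","cl01","s1",1.335,9,0,0,1,0,0,0,0,0,"fixture"
"c000002","cl01","s1",0.835,10,1,0,0,0,0,0,0,0,"fixture"
"c000003","cl01","s1",0.981,19,0,1,0,1,1,0,0,0,"fixture"
"c000004","cl01","s1",0.716,23,0,1,0,0,0,0,0,0,"fixture"
"c000005","cl01","s1",0.943,20,1,1,1,0,0,0,1,0,"fixture"
"c000006","cl02","s1",0.72,13,1,0,0,0,0,0,0,0,"fixture"
"c000007","cl02","s1",0.657,8,0,0,0,1,0,1,0,0,"fixture"
"c000008","cl02","s1",1.319,6,1,0,0,0,0,0,0,0,"fixture"
"c000009","cl02","s1",1.224,15,1,0,0,1,1,0,1,0,"fixture"
"c000010","cl02","s1",1.198,16,0,0,0,0,0,0,0,1,"fixture"
"c000011","cl03","s2",0.929,23,1,0,0,0,0,0,0,0,"fixture"
"c000012","cl03","s2",0.927,8,1,0,0,0,0,0,1,0,"fixture"
"c000013","cl03","s2",1.059,22,0,0,1,0,0,0,1,1,"fixture"
"c000014","cl03","s2",1.045,23,1,1,1,0,1,1,0,0,"fixture"
"c000015","cl03","s2",0.874,11,1,0,0,0,0,0,0,0,"fixture"
"c000016","cl04","s2",1.24,6,1,0,1,0,0,0,0,0,"fixture"
"c000017","cl04","s2",0.825,22,0,0,0,0,1,0,0,0,"fixture"
"c000018","cl04","s2",0.803,12,1,0,0,1,0,0,0,0,"fixture"
"c000019","cl04","s2",0.785,9,1,0,0,1,0,0,1,0,"fixture"
"c000020","cl04","s2",1.117,18,1,1,1,0,1,1,0,0,"fixture"
"c000021","cl05","s3",0.882,19,0,1,0,1,0,0,1,1,"fixture"
"c000022","cl05","s3",1.009,10,1,1,0,0,1,0,0,0,"fixture"
"c000023","cl05","s3",0.667,7,1,1,0,0,1,0,0,0,"fixture"
"c000024","cl05","s3",1.078,23,0,1,0,0,0,0,1,0,"fixture"
"c000025","cl05","s3",0.779,22,1,1,1,0,1,0,0,0,"fixture"
"c000026","cl06","s3",0.901,15,0,0,0,0,0,0,0,0,"fixture"
"c000027","cl06","s3",1.133,23,1,0,0,0,0,0,0,1,"fixture"
"c000028","cl06","s3",0.991,18,1,1,0,0,1,1,0,0,"fixture"
"c000029","cl06","s3",1.038,21,0,1,1,0,0,1,0,0,"fixture"
"c000030","cl06","s3",1.143,22,1,1,1,0,0,0,0,0,"fixture"
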