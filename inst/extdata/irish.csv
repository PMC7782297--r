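sample_id,DYS456,DYS389I,DYS390,DYS389II,DYS458,DYS19,DYS385,DYS393,DYS391,DYS439,DYS635,DYS392,YGATAH4,DYS437,DYS438,DYS448,ethnicity,paternal_origin_country,note
I1,15,13,24,29,17,15,11;14,13,11,11,23,13,12,15,12,19,Caucasian,Ireland,
I2,15,13,23,29,15,14,14;17,12,11,12,22,11,12,14,9,21,Caucasian,Ireland,
I3,16,12,24,29,16,14,11;14,13,11,12,23,13,12,15,12,19,Caucasian,Ireland,
I4,16,13,24,29,17,14,11;14,13,10,13,23,13,11,15,12,19,Caucasian,Ireland,
I5,15,13,24,30,17,14,11;14,14,10,12,23,13,11,15,12,19,Caucasian,Ireland,
I6,18,15,24,33,17,15,12;16,13,11,11,21,12,11,15,10,20,Caucasian,Ireland,
I7,15,13,24,29,18,14,11;14,13,11,11,23,13,13,15,12,19,Caucasian,Ireland,
I8,16,13,23,30,17,15,11;15,13,11,12,23,13,11,15,12,19,Caucasian,Ireland,
I9,16,13,25,29,17,14,11;13,13,11,12,23,14,12,15,12,18,Caucasian,Ireland,consistent with the Dal Riata founder haplotype except at DYS389II
I11,15,13,24,29,17,14,10;14,13,11,11,23,13,12,15,12,19,Caucasian,Ireland,
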