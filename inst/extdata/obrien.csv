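sample_id,DYS456,DYS389I,DYS390,DYS389II,DYS458,DYS19,DYS385,DYS393,DYS391,DYS439,DYS635,DYS392,YGATAH4,DYS437,DYS438,DYS448,surname_group,ethnicity,paternal_origin_country,paternal_origin_county,birthplace,note
OB1,16,12,24,28,18,14,11;14,13,11,12,23,13,12,15,12,19,O'Brien,Caucasian,Ireland,Kerry,,
OB2,15,12,22,28,15,14,13;14,12,10,12,21,11,10,16,10,20,O'Brien,Caucasian,Ireland,,,
OB3,17,14,23,30,16,14,12;14,13,11,13,23,13,13,14,12,19,O'Brien,Caucasian,Ireland,Limerick,,
OB4,16,14,23,31,16,14,11;15,13,11,13,23,13,12,15,12,19,O'Brien,Caucasian,Ireland,,,
OB5,16,13,25,29,17,14,11;13,13,10,12,23,14,12,15,12,18,O'Brien,Caucasian,Ireland,Clare,"West Haven, CT",same coincidental haplotype as OB6; not known to be genetically related
OB6,16,13,25,29,17,14,11;13,13,10,12,23,14,12,15,12,18,O'Brien,Caucasian,Ireland,Clare,"West Haven, CT",same coincidental haplotype as OB5; not known to be genetically related
OB7,16,14,24,31,18,14,11;14,13,11,11,23,13,12,15,12,18,O'Brien,Caucasian,Ireland,,,
OB8,17,14,24,31,17,15,11;15,13,10,10,21,11,11,15,10,20,O'Brien,Caucasian,Ireland,Roscommon,,
OB9,17,13,25,29,16,14,11;14,13,11,13,23,13,12,15;16,12,18,O'Brien,Caucasian,Ireland,,,consistent with the Dal Riata founder haplotype except at DYS389II
OB11,15,13,25,29,18,14,11;14,13,11,11,23,13,12,15,12,19,O'Brien,Caucasian,Ireland,Limerick,,consistent with the Dal Riata founder haplotype except at DYS389II
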