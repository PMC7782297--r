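name,DYS389I,DYS390,DYS389II,DYS458,DYS19,DYS385,DYS393,DYS391,DYS439,DYS392,YGATAH4,DYS437,DYS438,DYS448
obrien_footprint,13,24,29,17,14,11;14,13,11,11,13,11,15,12,19
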