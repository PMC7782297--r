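name,DYS393,DYS390,DYS19,DYS391,DYS389I,DYS389II
dal_riata,13,25,14,11,13,16
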