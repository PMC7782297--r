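name,DYS19,DYS390,DYS391,DYS393
sykes,15,23,11,14
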