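# synthetic demo signature (10 genes)
SIG001
SIG002
SIG003
SIG004
SIG005
SIG006
SIG007
SIG008
SIG009
SIG010
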