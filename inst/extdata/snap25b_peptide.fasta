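>SNAP25b_111-120 decapeptide appended to GST; numbering offset 111
GVVASQPARV
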