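>HTT_494-502 mutated region; IITEQP anchored at 494, residues 501-502 synthetic padding
IITEQPRGS
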