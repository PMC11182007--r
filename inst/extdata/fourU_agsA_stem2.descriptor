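# fourU RNA thermometer search descriptor (agsA second-stem scaffold):
# four consecutive U residues paired with the Shine-Dalgarno block AGGAG,
# ending at an anchored AUG start codon.
s1 h1 s2 h2 s3 h2' s4 h1' s5
s1 0   NNN******
h1 0:0 *NNNNN:NNNNN*
s2 0   N*
h2 0:0 *CUUUUNNNN*:*NNNNAGGAG*
s3 0   NNN****
s4 0   N*
s5 0   NAUG***
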