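// conservation of site 3 across the whole tree
global(x3=G)
// no reversions anywhere in the alignment
detectBM(4)
// probability of reaching base A at site 1 within 5 time units
P=?[F<=5 x1=A]
// minimum probability starting from states carrying C at site 1
filter(min, P=?[F<=5 x1=A], x1=C)
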