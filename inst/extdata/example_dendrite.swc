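# Synthetic example morphology: soma at origin, one 40 um dendrite along x
# branching into a 40 um leg along y (SWC: id type x y z radius parent).
1 1 0 0 0 8 -1
2 3 10 0 0 1.2 1
3 3 20 0 0 1.1 2
4 3 30 0 0 1.0 3
5 3 40 0 0 1.0 4
6 3 40 10 0 0.9 5
7 3 40 20 0 0.9 6
8 3 40 30 0 0.8 7
9 3 40 40 0 0.8 8
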