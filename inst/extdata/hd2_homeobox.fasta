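>HD2_PC15_homeobox homeobox DNA-binding motif fragment of the HD2 protein, strain PC15 (residue 179 onward)
MARKSMMTDRQIEVWFQNHRNSR
>HD2_PC9_homeobox homeobox DNA-binding motif fragment of the HD2 protein, strain PC9 (residue 177 onward)
MARKSMMTERQIEVWFQNHRNRAR
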