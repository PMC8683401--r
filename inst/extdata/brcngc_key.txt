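# BrCNGC-specific consensus motif key (CNBD: PBC + hinge region),
# induced from the family multiple sequence alignment at >90% conservation.
# 22 elements; span 39-53 residues.
[L]-X(2)-[G]-X(3)-[G]-X(1,2)-L-L-X-W-X(0,1,2)-[L]-X(7,14)-[P]-X(1,5)-S-X(10)-[E]-X-[F]-X-L
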