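# Hydrogen 1s Slater wavefunction, bonded-atom convention (zeta = 1.15 1/bohr).
# Format: ELEMENT <symbol> <Z> <charge> / ORBITAL <label> <l> <occupation> /
#         PRIM <n> <zeta 1/bohr> <contraction coefficient>
ELEMENT H 1 0
ORBITAL 1s 0 1
PRIM 1 1.15 1
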