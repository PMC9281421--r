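# Bundled example data

`frd_12state_fc_diagonal_only.json` — 12-state LVC model for the
adenine–thymine Watson–Crick pair at the ground-state equilibrium geometry,
fragment-diabatization convention. The diagonal diabatic energies, state
characters, irreps and oscillator strengths are transcribed from published
CAM-B3LYP/6-31G(d) values; the constant off-diagonal couplings of the full
diabatic Hamiltonian are not publicly printed and are therefore **set to
zero**, making this a partial (diagonal-only) transcription. Diagonalizing it
reproduces the published reference-point adiabatic energies only up to the
neglected couplings (deviations up to ~0.08 eV for the strongly coupled
states); the worked-example test documents exactly this gap. The file has no
normal modes: it describes the reference-point electronic block only.
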