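# Demonstration run: 200 kb synthetic genome with planted genome-defense
# ground truth.  Fixed placements are listed first; everything else is
# placed at random (deterministically, given the seed).
seed: 42
simulate:
  n_chrom: 2
  chrom_length: 100000
  gc_background: 0.55
  rip_rate: 0.10
  n_genes: 8
  background_read_rate: 2
  families:
    - family_id: cluster1      # clustered, silent, RIP'd + methylated:
      unit_length: 900         # the planted "defense region"
      n_copies: 5
      target_identity: 1.0
      strand_mix: 0
      superfamily: LTR
      expressed_frac: 0
      unit_gc: 0.42
      chrom: chr2
      start: 60000
    - family_id: gypsy1
      unit_length: 1500
      n_copies: 6
      target_identity: 0.95
      superfamily: LTR
      expressed_frac: 0.3
    - family_id: copia1
      unit_length: 800
      n_copies: 5
      target_identity: 0.90
      superfamily: LTR
      expressed_frac: 0.4
    - family_id: line1
      unit_length: 1200
      n_copies: 4
      target_identity: 0.92
      superfamily: LINE
      expressed_frac: 0.5
    - family_id: tir1
      unit_length: 600
      n_copies: 5
      target_identity: 0.95
      superfamily: TIR
      expressed_frac: 0.4
    - family_id: mite1         # unRIP'd, unmethylated DNA-transposon family
      unit_length: 450
      n_copies: 4
      target_identity: 0.97
      superfamily: MITE
      rip: false
      methylated: false
      expressed_frac: 0.5
  smrna_loci:
    - class: milRNA
      chrom: chr1
      start: 20000
    - class: milRNA
      chrom: chr1
      start: 50000
      strand: "-"
    - class: disiRNA
      chrom: chr2
      start: 20000
    - class: disiRNA
      chrom: chr2
      start: 30000
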