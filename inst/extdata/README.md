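# Example data

All files here are **synthetic**, produced by the package's own simulator
(`simulate_community()` / `write_simulation()` with seed 42: one 500 bp
replicon, two strain haplotypes, SNV rate 0.01 with gaps capped at 130 bp,
2 x 60 bp paired-end reads at 15x per strain, no read errors).

- `example_ref.fasta` — the base reference replicon
- `example.sam` — coordinate-sorted ground-truth alignments of the reads
- `example_truth.tsv` — engineered SNV sites with per-strain alleles
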