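# Bundled fixtures (all synthetic, hand-written)

## toy_sample{A,B,C,D}.cgmap

A 4-sample, 10-site CW cohort on chr1 (positions 100..1000, all forward
strand, CA dinucleotide) used to exercise the recurrent-site rules
(coverage >= 4 reads in >= 4 samples for the background; per-sample top
10% by level, recurrent in >= 75% of covered samples for the foreground).

Expected site sets under the default parameters:

* background: positions 100, 200, 300, 400, 500, 600, 700, 800
  (position 900 has coverage 3 everywhere; position 1000 reaches
  coverage >= 4 in only three samples).
* per-sample flags: 8 eligible sites each, so ceiling(0.1 * 8) = 1 site
  flagged per sample — position 100 in samples A, B, C and position 200
  in sample D.
* foreground: position 100 only (flagged in 3/4 = 75% of its covered
  samples; position 200 reaches 1/4 = 25%).
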