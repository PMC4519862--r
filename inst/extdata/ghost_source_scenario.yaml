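# Ghost-source invasion scenario: the Japanese population (Sa) is founded
# from an unsampled source, followed by a serial introduction Sa -> NJ;
# the US population (La) shares only the ghost ancestry.  Times are in
# generations, sizes in individuals.
name: ghost_source
populations:
  - {name: La, sampled: yes, size: N1}
  - {name: Sa, sampled: yes, size: N2}
  - {name: NJ, sampled: yes, size: N3}
  - {name: ghost, sampled: no, size: N4}
events:
  - {time: t1, source: Sa, target: NJ, founder: Nf3, duration: db}
  - {time: t2, source: ghost, target: Sa, founder: Nf2, duration: db}
  - {time: t3, source: ghost, target: La, founder: Nf1, duration: db}
priors:
  t1: {dist: unif, min: 1, max: 100}
  t2: {dist: unif, min: 1, max: 100}
  t3: {dist: unif, min: 1, max: 100}
  db: {dist: unif, min: 5, max: 25}
  N1: {dist: unif, min: 1000, max: 1.0e+6}
  N2: {dist: unif, min: 1000, max: 1.0e+6}
  N3: {dist: unif, min: 1000, max: 1.0e+6}
  N4: {dist: unif, min: 1000, max: 1.0e+6}
  Nf1: {dist: unif, min: 1, max: 10000}
  Nf2: {dist: unif, min: 1, max: 10000}
  Nf3: {dist: unif, min: 1, max: 10000}
orderings:
  - [t1, t2, t3]
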