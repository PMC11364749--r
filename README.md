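# pulsesort

Label-free cell sorting on multi-angle scattered-light pulse shapes: a
tested, fully synthetic implementation of the cluster-sort computational
pipeline used in pulse-shape flow cytometry.

## Who this is for

Flow-cytometry method developers and computational biologists who want to
study — without an instrument — how sorting on *pulse shapes* behaves: which
waveform features separate cell populations, how cluster-conjunction sort
criteria are ranked and chosen, and how mechanical sorter timing
(coincidence co-sorting, refractory rate limits) degrades purity and yield.

## The method

A pulse-shape cytometer records the full detector waveform of every cell
transit — 80 samples at 10 MHz over an 8 µs trigger window — in several
scattered-light channels (side scatter plus forward scatter resolved into
multiple collection angles). The pipeline is:

1. **Features.** Per channel, the deepest orthonormal Haar detail
   coefficients, one per 16-sample block:
   `c_b = (Σ first 8 − Σ last 8) / 4` — exactly 5 coefficients per channel
   from an 80-sample window — plus conventional area/height/width scalars.
2. **Cluster models.** Per-channel k-means (Lloyd + k-means++, default
   k = 6, at most 8) in 5-D coefficient space. The real-time decision rule
   is nearest-centroid by Euclidean distance, ties to the lowest id.
3. **Sort clusters.** All conjunctions (logical AND) of single-channel
   clusters from two different channels. Against reference labels, each
   cluster's enrichment in population *P* is
   `x(P,c) = (N(P,c)/N(·,c)) / (N(P,·)/N(·,·))`, with maximum achievable
   value `1/prevalence(P)`. Two rankings (top enrichment; largest clusters
   above a threshold fraction of the maximum, default 75%) are combined to
   select 3 sort clusters per population.
4. **Virtual sorter.** Discrete-event catcher-tube model: a full-match
   trigger engages the tube over `[t+200 µs, t+600 µs]`; any event arriving
   at the sort point (trigger + 300 µs) while engaged is deflected;
   triggers within the refractory period (default 1/300 s — the ~300
   events/s mechanical ceiling) are dropped. Sorted samples are re-analysed
   for purity and enrichment.

A built-in simulator generates multi-channel pulse streams (Poisson
arrivals, skew-normal transit profiles with population-specific height,
length, peak shift and extinction, Gaussian noise, trigger jitter) with
ground-truth labels, so every stage is testable end to end.

## Worked example

```r
library(pulsesort)
cfg <- run_config(event_rate = 1000, duration = 10, seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
Pipeline result: 10018 events, 216 candidate conjunction clusters
Sort selection: 9 clusters over 3 populations (threshold 75% of x_max)
  G1 (x_max = 2.18):
    FSC23:3&FSC8:1           x =  2.178  size = 20.75%
    FSC23:0&FSC8:0           x =  2.178  size = 19.86%
    SSC:0&FSC8:1             x =  2.178  size = 16.38%
  S (x_max = 2.9):
    FSC8:2&FSC4:5            x =  2.898  size = 14.47%
    SSC:4&FSC4:1             x =  2.896  size = 13.07%
    FSC23:1&FSC4:5           x =  2.898  size = 12.78%
  G2M (x_max = 5.11):
    SSC:2&FSC4:0             x =  5.106  size = 19.15%
    SSC:2&FSC23:2            x =  5.106  size = 11.11%
    FSC23:2&FSC4:0           x =  5.106  size = 10.87%
  sorted G1   via FSC23:3&FSC8:1           purity(G1) = 0.836, yield = 0.623
  sorted S    via FSC8:2&FSC4:5            purity(S) = 0.798, yield = 0.703
  sorted G2M  via SSC:2&FSC4:0             purity(G2M) = 0.770, yield = 0.645
```

Reading this: ~10⁴ simulated events over three populations (G1/S/G2M
morphologies, abundances 45/35/20%) produced 216 candidate two-channel
conjunction clusters; 9 were selected (3 per population). `x` is the
enrichment of the cluster in its target population — e.g. `SSC:2&FSC4:0`
(events in SSC cluster 2 *and* FSC4 cluster 0) reaches x = 5.11, the
maximum achievable for a 19.6%-prevalence population, i.e. an essentially
pure cluster holding 19% of all events. The virtual sort at 1000 events/s
then deflects that cluster with purity 0.77: coincident neighbours are
co-sorted at this rate, and yield 0.65 reflects full matches lost to the
refractory window. `run_pipeline(cfg, out_dir = "run")` additionally writes
the pulse/coefficient binaries, the FCS feature file, centroid and
selection tables, and index files.

A command-line front end over the same functions is in
`inst/scripts/pulsesort.R` (sub-commands `simulate`, `features`, `cluster`,
`rank`, `sort`, `pipeline`).

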