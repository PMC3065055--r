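# vasctum

A hybrid cellular automaton model of glioblastoma growth in a
vascularized tissue, with vascular-targeting treatment protocols.

Solid tumours in well-vascularized organs such as the brain first coopt
the host vasculature; the coopted vessels are destabilized through the
Ang-2/Tie-2 axis and regress unless rescued by VEGF, and the resulting
hypoxia drives VEGF-gradient angiogenic sprouting. `vasctum` implements
this cooption–regression–growth cycle as a daily-step simulator for
researchers studying how angiogenesis inhibitors (AI, bevacizumab-like),
cytotoxic chemotherapy (temozolomide-like) and vascular disrupting agents
(VDA, CA4P-like) shape tumour growth.

The model couples:

* an irregular automaton lattice — the Voronoi tessellation of an RSA
  hard-disk point process, one cell ≈ a cluster of seven glial cells
  (≈ 106 µm);
* a randomized Krogh-type capillary network with explicit flow
  dependencies, so destroying a vessel segment destroys everything it
  alone supplied;
* an eight-species reaction–diffusion system (VEGF, Ang-1, Ang-2, free and
  bound VEGFR-2 and Tie-2) solved one simulated day per automaton step;
* distance-to-vessel oxygenation rules with stochastic division

      p_div = p0 (1 - r/R_max),
      p0    = (p_min - p_max)/l_prolif * d_vessel + p_max,

  where `p_min = 0.1`, `p_max = 0.284` (doubling times of ~7 and ~3 days),
  `l_prolif = 250 µm` is the oxygen diffusion length and `R_max = 10 mm`
  the mechanical confinement radius;
* treatment protocols triggered at a 4 mm tumour radius: AI every two
  weeks (continuously effective), cytotoxic daily for six weeks, VDA every
  three weeks acting on dose days only.

## Worked example

```r
library(vasctum)

cfg <- simulation_config(
  seed = 1, domain = c(8, 8), total_days = 200,
  protocol = treatment_protocol(drugs = "AI", T1 = 100,
                                trigger_radius = 2))
res <- run_simulation(cfg)
print(res)
#> simulation: 200 days, tumor 14.79 mm^2 (active 8.03), radius 2.17 mm, trigger day 136

tail(res$metrics[, c("day", "proliferative", "hypoxic", "necrotic",
                     "tumor_area", "active_area", "radius")], 3)
#>     day proliferative hypoxic necrotic tumor_area active_area   radius
#> 199 198             0     750      631   14.79056    8.037044 2.169788
#> 200 199             0     750      631   14.79056    8.037044 2.169788
#> 201 200             0     749      632   14.79056    8.028890 2.169788
```

The tumour reached the 2 mm trigger radius on day 136; by day 200 the
inhibitor has frozen the active region (proliferative + hypoxic area,
8.0 mm²) while the total tumour area (14.8 mm², including the necrotic
core) records the growth that happened before and during early treatment —
the characteristic AI response: arrest without eradication.

`render_snapshot()` draws the standard colour convention (white viable
tissue, green apoptotic, blue proliferative, yellow hypoxic, black
necrotic; red native and purple angiogenic vessels);
`run_replicates()` and `sensitivity_sweep()` produce the averaged
treatment-response curves. A thin command-line front end is installed at
`inst/cli/vasctum` (`run`, `replicates`, `sweep`, `render`,
`calibrate-rvcrit`) over YAML configurations (`read_config()`).

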