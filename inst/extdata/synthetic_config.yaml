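# Example run configuration for two synthetic countries.
# (All names and numbers are synthetic; see ?run_config.)
countries:
  Norlandia:
    resolution: monthly
    basis: per_event
    top_fraction: 0.10
    years: [2013, 2020]
  Yearvia:
    resolution: yearly
    basis: per_year
    top_fraction: 0.50
synthetic:
  Norlandia:
    start: "2013-01-01"
    end: "2020-12-01"
    resolution: monthly
    base_rate: 1.2
    rate_trend: 0.01
    magnitude:
      family: lognormal
      meanlog: 10.6
      sdlog: 1.2
    seed: 101
  Yearvia:
    start: "2012-01-01"
    end: "2021-01-01"
    resolution: yearly
    base_rate: 12
    magnitude:
      family: lognormal
      meanlog: 11.0
      sdlog: 1.0
    seed: 202
run_trend: true
run_evt: true
out_dir: mme-report
seed: 1
q: 0.999
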