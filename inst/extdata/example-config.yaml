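# Example uvcast pipeline configuration.
# Paths are relative to the working directory in which the commands run.
paths:
  series: data/series.csv        # long-format datetime,value_mw_m2
  cloud: data/cloud.csv          # optional: datetime,name,value (daily)
  out_dir: uvcast-out
grid:
  start: "05:00"
  end: "19:00"
  step: 10                       # minutes
imputation:
  slot_window: 2
  day_window: 5
  year_window: 2
quality:
  max_abs_skewness: 0.3
  max_ratio: 15
  ceiling: 400                   # mW/m2
  floor: 150                     # mW/m2
smoothing:
  window: 11                     # Savitzky-Golay, inputs only
  polyorder: 3
windows:
  K: 14                          # past days fed to the encoder
  lead: 1                        # 1 = next-day forecast
model:
  encoder_hidden: [128, 256]
  dense_hidden: 160
  dropout: 0.2
  quantile_q: 0.33
train:
  lr_init: 0.0005
  lr_decay: 1.0e-7
  epochs: 2000
  batch_size: 256
  seed: 1
splits:
  train_years: [2009, 2010, 2011, 2012, 2013, 2015, 2016, 2017]
  val_years: [2018]
  test_years: [2019]
  excluded_years: [2014]
evaluate:
  window: ["08:00", "16:00"]
  floor: 1
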