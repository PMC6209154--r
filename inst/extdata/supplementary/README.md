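# User-supplied supplementary tables

The exact reproduction of the published correlation tables needs two
CSV files that are not redistributable with this package. Place them
here (they are read by `tests/testthat/test-acceptance.R`):

## `s2_sessions.csv` — session-level dynamics (one row per session x band)

Columns:

- `session` (1–6), `band` (`theta`/`alpha`/`beta`/`gamma`)
- `recruitment_motor`, `recruitment_cognitive`, `recruitment_visual`
- `integration_motor_visual`, `integration_motor_cognitive`,
  `integration_visual_cognitive`
- `avg_practice_time` (seconds), `avg_practice_gap` (days),
  `avg_performance` (0–100 scale)

Feed to `build_session_report()`.

## `s3_features.csv` — recording-level features (one row per recording)

Columns: `CT` (s), optional `Distraction`, `LE`, `HE`, `MW` pass-through
cognitive scores, `APA`, `AI`, `strength_theta` … `strength_gamma`,
`communication_theta` … `communication_gamma`, the eight FSRS metric
columns (`clutch_usage`, `left_tool_grasp`, `left_tool_out_of_view`,
`n_errors`, `right_tool_grasp`, `right_tool_out_of_view`,
`tissue_damage`, `tool_collision`), `D` (4–80) and `complexity` (1–5).

Feed to `build_feature_report()` and `build_difficulty_report()`.
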