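# Demonstration pipeline configuration: a small 3-subject cohort with
# shortened stages. See ?pipeline_config for every key and its default.
n_subjects: 3
seed: 11
synth:
  duration_per_stage: [20, 30, 10, 30, 15]
  cpb_gap_s: 20
  cautery_gaps:
    - [2, 10, 4]
summary_params: [dv, ri_forehead, a_mc]
tsne_subjects: [1]
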