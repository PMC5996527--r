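# Default catalogue of 16 heat-wave definitions: temperature metric x
# threshold rule x minimum consecutive-day duration. Percentiles are resolved
# against the reference series at detection time.
- {id: hw01, metric: mean, threshold_kind: percentile, threshold_value: 92.5, min_duration: 2}
- {id: hw02, metric: mean, threshold_kind: percentile, threshold_value: 92.5, min_duration: 3}
- {id: hw03, metric: mean, threshold_kind: percentile, threshold_value: 95.0, min_duration: 2}
- {id: hw04, metric: mean, threshold_kind: percentile, threshold_value: 95.0, min_duration: 3}
- {id: hw05, metric: mean, threshold_kind: percentile, threshold_value: 97.5, min_duration: 2}
- {id: hw06, metric: mean, threshold_kind: percentile, threshold_value: 97.5, min_duration: 3}
- {id: hw07, metric: mean, threshold_kind: percentile, threshold_value: 98.0, min_duration: 2}
- {id: hw08, metric: mean, threshold_kind: percentile, threshold_value: 98.0, min_duration: 3}
- {id: hw09, metric: max, threshold_kind: percentile, threshold_value: 92.5, min_duration: 2}
- {id: hw10, metric: max, threshold_kind: percentile, threshold_value: 92.5, min_duration: 3}
- {id: hw11, metric: max, threshold_kind: percentile, threshold_value: 95.0, min_duration: 2}
- {id: hw12, metric: max, threshold_kind: percentile, threshold_value: 95.0, min_duration: 3}
- {id: hw13, metric: max, threshold_kind: percentile, threshold_value: 97.5, min_duration: 2}
- {id: hw14, metric: max, threshold_kind: percentile, threshold_value: 97.5, min_duration: 3}
- {id: hw15, metric: max, threshold_kind: absolute, threshold_value: 35.0, min_duration: 2}
- {id: hw16, metric: max, threshold_kind: absolute, threshold_value: 35.0, min_duration: 3}
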