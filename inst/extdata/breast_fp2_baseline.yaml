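# Published FP2 approximation to the log baseline cumulative hazard of a
# node-positive primary breast cancer prognostic model (recurrence-free
# survival, time in years, follow-up truncated at 84 months):
#   ln H0(t) = 1.727 - 3.759 * t^-0.5 - 0.356 * t^-0.5 * ln t
# The reported fit explained 99.9% of the variation in ln H0(t).
powers:
- -0.5
- -0.5
coefficients:
- 1.727
- -3.759
- -0.356
r_squared: 0.999
time_range:
- 0.0833
- 7.0
time_unit: years
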