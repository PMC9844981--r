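# Expert-elicited 95% prior intervals for the three bias parameters:
#   P1    - prevalence of insufficient HIV-transmission knowledge among
#           unsafe injectors
#   P0    - the same prevalence among low-risk injectors
#   RR_UY - risk ratio of insufficient knowledge on not being tested
expert1:
  - {parameter: P1, lower: 0.025, upper: 0.095}
  - {parameter: P0, lower: 0.01, upper: 0.06}
  - {parameter: RR_UY, lower: 1.1, upper: 2.2}
expert2:
  - {parameter: P1, lower: 0.20, upper: 0.40}
  - {parameter: P0, lower: 0.10, upper: 0.20}
  - {parameter: RR_UY, lower: 1.1, upper: 5.0}
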