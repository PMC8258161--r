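# Annotated example of the tracer catalogue read by parse_tracer_spec().
#
# Per substrate: the commercially available isotopic species with their
# positional 13C pattern (one 0/1 entry per carbon, position 1 first),
# isotopic purity in atom% 13C at the labeled positions, and price in $/g.
# The chemostat block parameterizes the required substrate amounts:
# grams = concentration (g/L) x dilution rate (1/h) x working volume (L)
#         x duration, with duration = residence_times / dilution_rate.
chemostat:
  dilution_rate: 0.03      # 1/h
  working_volume: 0.25     # L
  residence_times: 5       # isotopic stationarity after ~5 residence times
substrates:
  - id: SA
    concentration: 20      # g/L in the feed medium
    species:
      - label: U-13C3      # uniformly labeled
        pattern: [1, 1, 1]
        purity: 99
        price: 640.0
      - label: 1-13C1      # labeled at carbon 1 only
        pattern: [1, 0, 0]
        purity: 99
        price: 250.0
      - label: 12C         # naturally labeled (unlabeled)
        pattern: [0, 0, 0]
        purity: 100
        price: 0.36
  - id: SB
    concentration: 0.17
    species:
      - label: U-13C2
        pattern: [1, 1]
        purity: 99
        price: 1500.0
      - label: 12C
        pattern: [0, 0]
        purity: 100
        price: 1.0
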