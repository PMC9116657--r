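# Residual deposit, literal-subtraction variant: the subadult residual is
# expected mass minus the collected urn mass (500 - 157 = 343 g). This
# reading is internally consistent as a model but does not reproduce the
# published residual budget total; see salorno_scenario_b_reproduced.yaml.
label: "Salorno B (literal subtraction; subadult residual 343 g)"
mode: residual
classes:
  - name: adult_male
    expected_mass_g: 2500
    collected_mass_g: 1695
    ratio: 1
  - name: adult_female
    expected_mass_g: 1800
    collected_mass_g: 1443
    ratio: 1
  - name: subadult
    expected_mass_g: 500
    collected_mass_g: 157
    ratio: 2
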