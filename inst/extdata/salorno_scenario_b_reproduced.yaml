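# Residual deposit after urn collection. Adult residuals are expected mass
# minus the reference urn masses (Novale di Sotto 1,695 g; Collalbo
# 1,443 g). The subadult residual is fixed by override at 157 g (the
# Frattesina-Le Narde subadult urn average used directly): this is the
# variant whose arithmetic reproduces the published residual budget total
# and MNI. Compare salorno_scenario_b_printed.yaml.
label: "Salorno B (residual; subadult override 157 g)"
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
    residual_override_g: 157
    ratio: 2
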