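# Primary deposition: every cremated individual contributes the full
# burnt-skeleton mass. Unit = 1 adult male : 1 adult female : 2 subadults.
label: "Salorno A (primary deposition)"
mode: primary
classes:
  - name: adult_male
    expected_mass_g: 2500
    ratio: 1
  - name: adult_female
    expected_mass_g: 1800
    ratio: 1
  - name: subadult
    expected_mass_g: 500
    ratio: 2
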