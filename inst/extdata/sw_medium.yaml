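# Synthetic high-ammonia-nitrogen wastewater (SW), major-ion totals.
# pH is the measured value of SW without sludge.
pH: 7.7
temperature_C: 25
activity_model: davies
components:
  NH4+: {total_mM: 18.10, charge: 1}
  Na+: {total_mM: 22.84, charge: 1}
  K+: {total_mM: 12.42, charge: 1}
  Ca+2: {total_mM: 0.01, charge: 2}
  Mg+2: {total_mM: 2.10, charge: 2}
  Cl-: {total_mM: 18.50, charge: -1}
  NO2-: {total_mM: 23.19, charge: -1}
  SO4-2: {total_mM: 2.03, charge: -2}
  CO3-2: {total_mM: 0.05, charge: -2}
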