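# IV fluid compositions, in the reporting units of each analyte:
# NA/K/CL/CO2 mmol/L, GLU mg/dL, CA mg/dL, BUN/CREAT mg/dL.
# Cellular analytes (HGB, PLT, WBC) are zero in every IV fluid, so CBC
# dilution is fluid-agnostic; composition matters only for chemistry panels.
normal_saline:
  NA: 154
  CL: 154
half_normal_saline:
  NA: 77
  CL: 77
d5w:
  GLU: 5000
d5_half_normal_saline:
  NA: 77
  CL: 77
  GLU: 5000
lactated_ringers:
  NA: 130
  K: 4
  CL: 109
  CA: 5.4
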