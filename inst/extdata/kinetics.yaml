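# Default kinetic parameters for the astrocytic glutamate transporter (EAAT)
# and the sodium-calcium exchanger (NCX).
#
# These are package defaults of literature order, not a published fit:
# the EAAT cycle follows the alternating-access scheme with separate binding
# and unbinding of 3 Na+, 1 H+, 1 Glu (extracellular side) and 1 K+
# countertransport (Bergles-type GLT-1 models); the NCX cycle is a 6-state
# consecutive (ping-pong) 3 Na+ : 1 Ca2+ exchange (Chu-type models). NCX base
# rates are calibrated to be exactly thermodynamically consistent, so the
# cycle flux vanishes at the reversal potential 3*E_Na - 2*E_Ca. Edit freely;
# the loader validates the schema and the simulator re-checks the 1 us
# Bernoulli step bound at run time.
#
# units:
#   per_ms       first-order rate, 1/ms
#   per_mM_ms    second-order rate, 1/(mM*ms); multiplied by the ligand
#                concentration in mM
#   per_mM3_ms   pseudo-first-order with cubic ligand dependence
# charge: elementary charge moved INTO the cell when the transition fires;
#   rates get the symmetric Eyring factor exp(-q*V / (2*RT/F)).
# action: particle-bookkeeping hook interpreted by the engine.

eaat:
  states: [out_apo, out_na, out_na_glu, out_na2_glu, out_na3_glu,
           out_na3_glu_h, in_na3_glu_h, in_na3_glu, in_na3, in_na2,
           in_na, in_apo, in_k]
  stoichiometry: {na_in: 3, h_in: 1, glu_in: 1, k_out: 1, charge_in: 2}
  transitions:
    - {from: out_apo,       to: out_na,        rate: 0.2,   units: per_mM_ms, ligand: na_e}
    - {from: out_na,        to: out_apo,       rate: 30,    units: per_ms}
    - {from: out_na,        to: out_na_glu,    rate: 5,     units: per_mM_ms, ligand: glu_e, action: glu_bind}
    - {from: out_na_glu,    to: out_na,        rate: 0.15,  units: per_ms,    action: glu_release_out}
    - {from: out_na_glu,    to: out_na2_glu,   rate: 0.2,   units: per_mM_ms, ligand: na_e}
    - {from: out_na2_glu,   to: out_na_glu,    rate: 30,    units: per_ms}
    - {from: out_na2_glu,   to: out_na3_glu,   rate: 0.2,   units: per_mM_ms, ligand: na_e}
    - {from: out_na3_glu,   to: out_na2_glu,   rate: 30,    units: per_ms}
    - {from: out_na3_glu,   to: out_na3_glu_h, rate: 1.0e4, units: per_mM_ms, ligand: h}
    - {from: out_na3_glu_h, to: out_na3_glu,   rate: 0.5,   units: per_ms}
    - {from: out_na3_glu_h, to: in_na3_glu_h,  rate: 0.4,   units: per_ms,    charge: 3}
    - {from: in_na3_glu_h,  to: out_na3_glu_h, rate: 0.4,   units: per_ms,    charge: -3}
    - {from: in_na3_glu_h,  to: in_na3_glu,    rate: 3,     units: per_ms}
    - {from: in_na3_glu,    to: in_na3_glu_h,  rate: 1.0e4, units: per_mM_ms, ligand: h}
    - {from: in_na3_glu,    to: in_na3,        rate: 1.0,   units: per_ms,    action: glu_release_in}
    - {from: in_na3,        to: in_na3_glu,    rate: 0.5,   units: per_mM_ms, ligand: glu_i, action: glu_load_in}
    - {from: in_na3,        to: in_na2,        rate: 25,    units: per_ms,    na_delta: 1}
    - {from: in_na2,        to: in_na3,        rate: 0.2,   units: per_mM_ms, ligand: na_i, na_delta: -1}
    - {from: in_na2,        to: in_na,         rate: 25,    units: per_ms,    na_delta: 1}
    - {from: in_na,         to: in_na2,        rate: 0.2,   units: per_mM_ms, ligand: na_i, na_delta: -1}
    - {from: in_na,         to: in_apo,        rate: 25,    units: per_ms,    na_delta: 1}
    - {from: in_apo,        to: in_na,         rate: 0.2,   units: per_mM_ms, ligand: na_i, na_delta: -1}
    - {from: in_apo,        to: in_k,          rate: 0.15,  units: per_mM_ms, ligand: k_i}
    - {from: in_k,          to: in_apo,        rate: 20,    units: per_ms}
    - {from: in_k,          to: out_apo,       rate: 1.0,   units: per_ms,    charge: -1}
    - {from: out_apo,       to: in_k,          rate: 0.05,  units: per_mM_ms, ligand: k_e, charge: 1}

ncx:
  states: [in_apo, in_ca, out_ca, out_apo, out_na3, in_na3]
  stoichiometry: {na_in: 3, ca_out: 1, charge_in: 1}
  transitions:
    - {from: in_apo,  to: in_ca,   rate: 300,   units: per_mM_ms,  ligand: ca_i, action: ca_bind_in}
    - {from: in_ca,   to: in_apo,  rate: 3,     units: per_ms,     action: ca_release_in}
    - {from: in_ca,   to: out_ca,  rate: 5,     units: per_ms,     charge: -2}
    - {from: out_ca,  to: in_ca,   rate: 5,     units: per_ms,     charge: 2}
    - {from: out_ca,  to: out_apo, rate: 40,    units: per_ms,     action: ca_release_out}
    - {from: out_apo, to: out_ca,  rate: 12,    units: per_mM_ms,  ligand: ca_e, action: ca_load_out}
    - {from: out_apo, to: out_na3, rate: 2.0e-5, units: per_mM3_ms, ligand: na_e}
    - {from: out_na3, to: out_apo, rate: 30,    units: per_ms}
    - {from: out_na3, to: in_na3,  rate: 1.0,   units: per_ms,     charge: 3}
    - {from: in_na3,  to: out_na3, rate: 1.0,   units: per_ms,     charge: -3}
    - {from: in_na3,  to: in_apo,  rate: 100,   units: per_ms,     na_delta: 3}
    - {from: in_apo,  to: in_na3,  rate: 0.022222222222222222, units: per_mM3_ms, ligand: na_i, na_delta: -3}
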