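# Canonical synthetic structures used across tests: a blank bilayer inside
# the experimentally reported parameter ranges, and a drug-loaded variant
# with one adsorbed layer.
blank_model <- function(rough_substrate = 3, rough_membrane = 3,
                        head_in = list(cpz = 0, solvent = 0.5),
                        head_out = list(cpz = 0, solvent = 0.5),
                        tail_in = list(cpz = 0, solvent = 0.05),
                        tail_out = list(cpz = 0, solvent = 0.05), ...) {
  membrane_model(variant = "BLANK", t_head = 8, t_tail = 17.5,
                 head_in = head_in, head_out = head_out,
                 tail_in = tail_in, tail_out = tail_out,
                 rough_substrate = rough_substrate,
                 rough_membrane = rough_membrane, ...)
}

cpz_1ad_model <- function(cpz = 0.2, ...) {
  membrane_model(variant = "CPZ_TAILS_1AD", t_head = 8, t_tail = 15,
                 tail_in = list(cpz = cpz, solvent = 0.05),
                 tail_out = list(cpz = cpz, solvent = 0.05),
                 adsorbed = list(list(thickness = 119, sld = 2.3,
                                      solvent = 0.96)),
                 ...)
}
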