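# shared fixtures, built in code

# the 7-turn murine flat spiral (package defaults restated explicitly so
# a default change would be caught)
murine_spec <- function(...) {
  args <- utils::modifyList(
    list(topology = "circular", inner_diameter_mm = 20,
         outer_diameter_mm = 65, turns = 7, wire_width_mm = 3,
         wire_height_mm = 2, turn_gap_mm = 0.2, current_A = 1000,
         voltage_V = 500, frequency_Hz = 20),
    list(...))
  do.call(coil_spec, args)
}

# a single filamentary loop of radius a_mm carrying current_A, as a
# winding_model (built through the public constructor with a degenerate
# one-turn spec)
single_loop <- function(a_mm = 10, current_A = 1000, wire_width_mm = 3) {
  spec <- coil_spec(inner_diameter_mm = 2 * a_mm - wire_width_mm,
                    outer_diameter_mm = 2 * a_mm + wire_width_mm,
                    turns = 1, wire_width_mm = wire_width_mm,
                    turn_gap_mm = 0.2, current_A = current_A,
                    validate = FALSE)
  build_winding(spec)
}
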