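# Shared fixtures, built once per test run. The "small" phantom keeps the
# physical extent of the default phantom (240 mm cube) on a coarser 48^3
# grid so organ geometry and motion amplitudes stay realistic while tests
# run fast.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(arms = FALSE) {
  phantom_config(dim = c(48, 48, 48), spacing = c(5, 5, 5), arms = arms)
}

small_pair <- function() {
  if (is.null(.fixtures$pair)) {
    .fixtures$pair <- generate_phantom_pair(
      small_config(), seed = 7,
      motion = motion_parameters(12, 4))
  }
  .fixtures$pair
}

small_phantom <- function() small_pair()$exhaled

# closed liver masks for registration scoring
closed_livers <- function() {
  if (is.null(.fixtures$livers)) {
    pair <- small_pair()
    .fixtures$livers <- list(
      fixed = close_liver_mask(
        extract_organ_mask(pair$exhaled, "liver"),
        extract_organ_mask(pair$exhaled, "hepatic_vessel")),
      moving = close_liver_mask(
        extract_organ_mask(pair$inhaled, "liver"),
        extract_organ_mask(pair$inhaled, "hepatic_vessel")))
  }
  .fixtures$livers
}
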