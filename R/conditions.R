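#' Define a simulated perturbation condition
#'
#' Three conditions are modelled. `"control"`: MTs are nucleated from the
#' nuclear envelope (NE), and both Kif5b (plus-end directed) and dynein
#' (minus-end directed) motors are anchored at the NE.
#' `"no_ne_nucleation"`: nucleation activity is removed from the NE and
#' assigned to centrosome-like bodies placed randomly in the cytoplasm; no
#' other feature changes, in particular NE Kif5b is retained.
#' `"no_ne_nucleation_no_kif5b"`: additionally removes Kif5b from the NE.
#' NE dynein is retained in all three conditions (toggle via the
#' `dynein_retained` parameter).
#'
#' @param name One of `"control"`, `"no_ne_nucleation"`,
#'   `"no_ne_nucleation_no_kif5b"`.
#' @param centrosomes_per_nucleus Number of cytoplasmic centrosome-like
#'   bodies per nucleus, used when NE nucleation is off.
#' @return An object of class `condition_spec` with fields `name`,
#'   `ne_nucleation`, `ne_kif5b`, `centrosomes_per_nucleus`.
#' @export
#' @examples
#' make_condition("control")
#' make_condition("no_ne_nucleation")
make_condition <- function(name = c("control", "no_ne_nucleation",
                                    "no_ne_nucleation_no_kif5b"),
                           centrosomes_per_nucleus = 1) {
  name <- match.arg(name)
  ne_nucleation <- name == "control"
  ne_kif5b <- name != "no_ne_nucleation_no_kif5b"
  structure(
    list(name = name,
         ne_nucleation = ne_nucleation,
         ne_kif5b = ne_kif5b,
         centrosomes_per_nucleus =
           if (ne_nucleation) 0 else centrosomes_per_nucleus),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s: NE nucleation %s, NE Kif5b %s, %g centrosome(s)/nucleus\n",
              x$name, if (x$ne_nucleation) "on" else "off",
              if (x$ne_kif5b) "on" else "off", x$centrosomes_per_nucleus))
  invisible(x)
}
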