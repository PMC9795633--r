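#' Built-in sampling designs of the two evolution experiments
#'
#' Elapsed bacterial generations at which whole-population sequencing was
#' performed. The mouse-host design covers the fifteen sequenced populations
#' of the first replicate line (mouse generations F0 through F4 plus the
#' 10-month F0 sample); the mouse-diet design covers transfers 2 and 14; the
#' fly designs cover experimental-evolution cycles 2, 8, 14 and 20 at 88
#' generations per cycle.
#'
#' @return `mouse_host_design()`: a `data.frame` with `sample_id` and
#'   `generations`; the `*_generations()` helpers return numeric vectors.
#' @export
mouse_host_design <- function() {
  data.frame(
    sample_id = c("F0-1", "F0-2", "F1-1", "F0-3", "F1-2", "F2-1", "F1-3",
                  "F2-2", "F2-3", "F3-1", "F3-2", "F4-1", "F3-3", "F0-10",
                  "F4-2"),
    generations = c(30, 60, 63, 90, 93, 110, 120, 150, 170, 200, 230, 240,
                    260, 280, 280),
    stringsAsFactors = FALSE)
}

#' @rdname mouse_host_design
#' @export
mouse_host_generations <- function() mouse_host_design()$generations

#' @rdname mouse_host_design
#' @export
mouse_diet_generations <- function() c(40, 280)

#' @rdname mouse_host_design
#' @export
fly_generations <- function() c(176, 704, 1232, 1760)

#' Hypermutator lineage-fraction schedule for the mouse-host design
#'
#' A two-mutator fraction schedule over the fifteen mouse-host samples that
#' mirrors the observed clonal-interference dynamics: the mutS A41T lineage
#' rises to ~90% in the F0 mouse over the first three months and then
#' collapses, while the mutS D1303 (frameshift) lineage sweeps to fixation in
#' the later mouse generations; in the F1 mice neither lineage exceeds 20%,
#' and in the F2 mice both rise to ~45% before crashing. Fractions sum to at
#' most 1 per sample; the remainder is the nonmutator background.
#'
#' @return matrix (samples x 2) with columns `A41T` and `D1303` and
#'   `sample_id` rownames.
#' @export
mouse_host_fraction_schedule <- function() {
  design <- mouse_host_design()
  sched <- rbind(
    c(0.40, 0.00),  # F0-1
    c(0.80, 0.02),  # F0-2
    c(0.10, 0.05),  # F1-1
    c(0.90, 0.05),  # F0-3
    c(0.15, 0.10),  # F1-2
    c(0.20, 0.15),  # F2-1
    c(0.10, 0.15),  # F1-3
    c(0.45, 0.45),  # F2-2
    c(0.02, 0.03),  # F2-3
    c(0.05, 0.60),  # F3-1
    c(0.02, 0.90),  # F3-2
    c(0.00, 0.95),  # F4-1
    c(0.00, 1.00),  # F3-3
    c(0.00, 1.00),  # F0-10
    c(0.00, 1.00))  # F4-2
  dimnames(sched) <- list(design$sample_id, c("A41T", "D1303"))
  sched
}
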