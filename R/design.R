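#' Default six-donor, three-experiment multiplex design
#'
#' Channel-to-sample assignment of the paired plasma study design: three
#' 4-plex experiments, each multiplexing two donors at baseline and after
#' remote ischemic preconditioning (RIPC). In experiments 1 and 3 the
#' baseline samples sit in channels 114/116; experiment 2 swaps the labels
#' so that RIPC sits in 114/116 (donor 3 RIPC in 114, donor 4 RIPC in 116),
#' guarding against systematic label bias.
#'
#' @return data.frame with columns \code{experiment_id}, \code{channel},
#'   \code{donor_id}, \code{condition} (\code{"baseline"}/\code{"ripc"}).
#' @export
default_design <- function() {
  data.frame(
    experiment_id = rep(c("exp1", "exp2", "exp3"), each = 4L),
    channel = rep(c(114L, 115L, 116L, 117L), times = 3L),
    donor_id = c(1L, 1L, 2L, 2L,
                 3L, 3L, 4L, 4L,
                 5L, 5L, 6L, 6L),
    condition = c("baseline", "ripc", "baseline", "ripc",
                  "ripc", "baseline", "ripc", "baseline",
                  "baseline", "ripc", "baseline", "ripc"),
    stringsAsFactors = FALSE
  )
}

# Check structural validity of a design table: each experiment has the four
# channels exactly once, and each of its donors has one baseline and one
# ripc channel.
validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("experiment_id", "channel", "donor_id", "condition")
                %in% names(design)))
  if (!all(design$condition %in% c("baseline", "ripc"))) {
    stop("design: condition must be 'baseline' or 'ripc'")
  }
  for (exp_id in unique(design$experiment_id)) {
    d <- design[design$experiment_id == exp_id, ]
    if (!setequal(d$channel, c(114L, 115L, 116L, 117L)) || nrow(d) != 4L) {
      stop(sprintf("design: experiment '%s' must use channels 114-117 exactly once",
                   exp_id))
    }
    for (donor in unique(d$donor_id)) {
      conds <- d$condition[d$donor_id == donor]
      if (!setequal(conds, c("baseline", "ripc"))) {
        stop(sprintf("design: donor '%s' in experiment '%s' needs one baseline and one ripc channel",
                     donor, exp_id))
      }
    }
  }
  invisible(design)
}
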