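#' Cumulative vestibular-syndrome score
#'
#' The qualitative vestibular-syndrome scale sums fixed weights over the
#' symptoms present: tumbling 5, retropulsion 4, circling 3, bobbing 2,
#' head tilt 1, giving an integer score between 0 (no syndrome) and 15
#' (all symptoms).
#'
#' @param checklist named logical vector or data.frame with columns
#'   `tumbling`, `retropulsion`, `circling`, `bobbing`, `head_tilt`;
#'   vectorized over data.frame rows.
#' @return integer score(s) in 0..15.
#' @export
syndrome_score <- function(checklist) {
  weights <- c(tumbling = 5L, retropulsion = 4L, circling = 3L,
               bobbing = 2L, head_tilt = 1L)
  if (is.data.frame(checklist)) {
    missing <- setdiff(names(weights), names(checklist))
    if (length(missing) > 0L) {
      stop("syndrome_score: missing symptom column(s): ",
           paste(missing, collapse = ", "))
    }
    m <- as.matrix(checklist[names(weights)])
    storage.mode(m) <- "logical"
    if (anyNA(m)) stop("syndrome_score: symptoms must be TRUE/FALSE")
    return(as.integer(m %*% weights))
  }
  missing <- setdiff(names(weights), names(checklist))
  if (length(missing) > 0L) {
    stop("syndrome_score: missing symptom(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- as.logical(checklist[names(weights)])
  if (anyNA(vals)) stop("syndrome_score: symptoms must be TRUE/FALSE")
  as.integer(sum(weights[vals]))
}
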