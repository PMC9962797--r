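#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols rename distinct pull n across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map2 pmap imap walk
#' @importFrom stats median quantile var sd cor prcomp pnorm pt rnorm rgamma
#'   runif setNames p.adjust complete.cases
#' @importFrom utils combn head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# run code under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards so library code never perturbs the session RNG
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# derive a stream of child seeds from one master seed, keeping values well
# inside 32-bit integer range
derive_seeds <- function(seed, n, offset = 0L) {
  (as.integer(seed) %% 1000000L) * 1000L + offset + seq_len(n)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x) && x > 0
}

# canonical unordered-pair key, used to deduplicate correlation records
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
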