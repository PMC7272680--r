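#' @keywords internal
"_PACKAGE"

# metadata columns shared by all subject-level tables
.meta_cols <- c("subject_id", "treatment", "age", "sex")

#' Deterministic 31-bit hash of a character string
#'
#' Polynomial rolling hash modulo 2^31 - 1, used to split one cohort-level
#' seed into independent per-group streams: adding or removing a group must
#' not reshuffle the draws of any other group.
#'
#' @param x single character string.
#' @return integer in `[0, 2^31 - 2]`.
#' @keywords internal
hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Derive a per-label sub-seed from a cohort seed
#'
#' @param seed non-negative integer cohort seed.
#' @param label character label (e.g. a group id).
#' @return integer seed below 2^31 - 1.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  as.integer((seed %% 2147483647 + hash31(label)) %% 2147483647)
}

#' Canonical group label
#'
#' @param treatment,age,sex vectors (recycled) of group metadata.
#' @return character vector like `"control_4_male"`.
#' @export
group_label <- function(treatment, age, sex) {
  paste(treatment, age, sex, sep = "_")
}

# stop() with sprintf formatting, no call in the condition
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
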