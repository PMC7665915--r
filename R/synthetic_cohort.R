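#' Specification of a synthetic user/nonuser cohort
#'
#' Describes a two-group cohort (herbal-medicine users vs nonusers) by its
#' group sizes and, per group, one probability vector for every categorical
#' or flag variable. Flags (comorbidities, conventional-treatment classes)
#' are given as the probability of the flag being set.
#'
#' @param n_users,n_nonusers group sizes.
#' @param probs named list with one entry per variable; each entry is a list
#'   with elements `users` and `nonusers`, each either a named probability
#'   vector over the variable's levels (categoricals) or a single
#'   probability in `[0,1]` (flags).
#' @param seed integer seed driving the generator.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ar_cohort_spec()]
#' @export
cohort_spec <- function(n_users, n_nonusers, probs, seed = 1L) {
  n_users <- check_count(n_users, "n_users")
  n_nonusers <- check_count(n_nonusers, "n_nonusers")
  stopifnot(is.list(probs), length(probs) > 0L, !is.null(names(probs)))
  for (v in names(probs)) {
    entry <- probs[[v]]
    if (!is.list(entry) || !all(c("users", "nonusers") %in% names(entry))) {
      stop("probs entry '", v, "' must list 'users' and 'nonusers'",
           call. = FALSE)
    }
    for (g in c("users", "nonusers")) {
      p <- entry[[g]]
      if (length(p) == 1L && is.null(names(p))) {
        if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
          stop("invalid probability vector for '", v, "' (", g, ")",
               call. = FALSE)
        }
      } else {
        check_prob_vector(p, paste0(v, " (", g, ")"))
        if (is.null(names(p))) {
          stop("categorical probabilities for '", v,
               "' must be named by level", call. = FALSE)
        }
      }
    }
  }
  structure(list(n_users = n_users, n_nonusers = n_nonusers,
                 probs = probs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws every variable independently from the per-group probability vectors
#' of the spec. Emulates the structure of a claims-database patient extract:
#' one row per patient with demographics, comorbidity flags, conventional
#' medication flags and a medication-type count band.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with `patient_id`, logical `chm_user`, and one
#'   column per variable in the spec (character for categoricals, logical
#'   for flags). Identical spec and seed give an identical table.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_users + spec$n_nonusers
  out <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    chm_user = rep(c(TRUE, FALSE), c(spec$n_users, spec$n_nonusers)),
    stringsAsFactors = FALSE
  )
  with_seed(derive_seed(spec$seed, "cohort"), {
    for (v in names(spec$probs)) {
      entry <- spec$probs[[v]]
      col <- vector(if (is.null(names(entry$users)) &&
                        length(entry$users) == 1L) "logical" else "character",
                    n)
      for (g in c("users", "nonusers")) {
        idx <- if (g == "users") out$chm_user else !out$chm_user
        p <- entry[[g]]
        if (length(p) == 1L && is.null(names(p))) {
          col[idx] <- runif(sum(idx)) < p
        } else {
          col[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
        }
      }
      out[[v]] <- col
    }
  })
  out
}
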