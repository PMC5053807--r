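#' Generate a picture-viewing-task recipe
#'
#' A recipe is the full trial list of one scanning session: every object
#' (including the target) appears exactly once per block, in a fresh random
#' order per block; inter-trial intervals of 2 or 3 TRs are balanced 50/50
#' across the session and assigned at random. Candidate recipes in which a
#' one-way ANOVA of trial position by object is significant (p < 0.05,
#' i.e. some object lands consistently early or late) are discarded and
#' regenerated. The accepted recipe is used verbatim for both the pre- and
#' the post-learning session.
#'
#' @param n_objects Objects per block, including the target (default 17;
#'   the target is the highest object id).
#' @param n_blocks Number of blocks (default 12).
#' @param seed Integer seed.
#' @param tr Repetition time in seconds (default 2.27).
#' @param break_trs Volumes inserted between blocks (default 13, ~30 s).
#' @param iti_choices Allowed stimulus-onset asynchronies in TRs.
#' @param anova_alpha Rejection level of the position ANOVA.
#' @param max_retries Upper bound on regeneration attempts.
#' @return Object of class `pvt_recipe`: `trials` (data frame with columns
#'   `trial`, `object`, `block`, `onset_volume` (0-based), `iti_tr`),
#'   `target_object`, `tr`, `n_objects`, `n_blocks`, `n_volumes`, and the
#'   position-ANOVA p of the accepted recipe.
#' @export
generate_pvt_recipe <- function(n_objects = 17L, n_blocks = 12L, seed = NULL,
                                tr = 2.27, break_trs = 13L,
                                iti_choices = c(2L, 3L), anova_alpha = 0.05,
                                max_retries = 100L) {
  stopifnot(n_objects >= 2, n_blocks >= 1, length(iti_choices) == 2)
  n_trials <- n_objects * n_blocks
  with_seed_or_current(seed, {
    for (attempt in seq_len(max_retries)) {
      object <- as.integer(unlist(lapply(seq_len(n_blocks),
                                         function(b) sample.int(n_objects))))
      block <- rep(seq_len(n_blocks), each = n_objects)
      # balanced ITI assignment; odd trial counts give the extra slot to
      # the first choice
      n2 <- ceiling(n_trials / 2)
      iti <- sample(rep(iti_choices, c(n2, n_trials - n2)))
      pos_p <- recipe_position_anova_p(object, seq_len(n_trials))
      if (pos_p > anova_alpha) {
        onset <- integer(n_trials)
        for (k in seq_len(n_trials - 1L)) {
          gap <- iti[k] + if (block[k + 1L] != block[k]) break_trs else 0L
          onset[k + 1L] <- onset[k] + gap
        }
        trials <- data.frame(trial = seq_len(n_trials), object = object,
                             block = block, onset_volume = onset,
                             iti_tr = iti)
        return(structure(
          list(trials = trials, target_object = as.integer(n_objects),
               tr = tr, n_objects = as.integer(n_objects),
               n_blocks = as.integer(n_blocks),
               n_volumes = onset[n_trials] + 4L,
               position_anova_p = pos_p),
          class = "pvt_recipe"
        ))
      }
    }
    stop(sprintf("no recipe passed the position ANOVA in %d attempts",
                 max_retries))
  })
}

# One-way F test of trial position by object identity.
recipe_position_anova_p <- function(object, position) {
  fit <- stats::aov(position ~ factor(object))
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' @export
print.pvt_recipe <- function(x, ...) {
  cat(sprintf(
    "<pvt_recipe: %d trials (%d objects x %d blocks), %d volumes, TR %gs>\n",
    nrow(x$trials), x$n_objects, x$n_blocks, x$n_volumes, x$tr))
  invisible(x)
}

#' Write / read a recipe trial table as TSV
#' @param recipe A `pvt_recipe`.
#' @param path Output file path.
#' @return `write_recipe` returns `path` invisibly; `read_recipe` returns a
#'   `pvt_recipe` (metadata columns are carried in a header comment).
#' @export
write_recipe <- function(recipe, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# target_object=%d tr=%g n_objects=%d n_blocks=%d n_volumes=%d",
                     recipe$target_object, recipe$tr, recipe$n_objects,
                     recipe$n_blocks, recipe$n_volumes), con)
  utils::write.table(recipe$trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  trials <- utils::read.delim(path, comment.char = "#")
  structure(
    list(trials = trials, target_object = as.integer(meta[1]), tr = meta[2],
         n_objects = as.integer(meta[3]), n_blocks = as.integer(meta[4]),
         n_volumes = as.integer(meta[5]),
         position_anova_p = NA_real_),
    class = "pvt_recipe"
  )
}
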