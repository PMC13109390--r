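#' Per-environment adjusted cultivar means (BLUEs)
#'
#' Fits a two-way fixed-effects model `value ~ genotype + block` to the plot
#' observations of one trait in one environment and returns each genotype's
#' adjusted mean: the model prediction averaged over the block levels of its
#' connected design component. With a single block, or a single plot per
#' genotype, this collapses to the plain mean. Technical replicates within a
#' block are averaged before fitting so they do not inflate the weight of a
#' genotype-block cell.
#'
#' Genotype-block incidence is checked for connectivity; disconnected
#' components are estimated separately, which prevents silently aliased
#' contrasts from leaking across components. A genotype whose effect is not
#' estimable is returned with a missing BLUE and a warning.
#'
#' @param plots Data frame of plot observations with columns `genotype`,
#'   `environment`, `block`, `trait`, `value`.
#' @param trait,environment The trait and environment to fit.
#' @return A tibble with columns `trait`, `environment`, `genotype`, `blue`,
#'   `se` (missing when only one plot supports the genotype or the model is
#'   saturated) and `n_rep`, the number of genotype-block cells supporting
#'   the estimate.
#' @export
#' @examples
#' plots <- data.frame(
#'   genotype = c("g1", "g1", "g2"), environment = "E1",
#'   block = c(1, 2, 1), trait = "yield", value = c(10, 12, 9)
#' )
#' fit_environment_blues(plots, "yield", "E1")
fit_environment_blues <- function(plots, trait, environment) {
  check_columns(plots, c("genotype", "environment", "block", "trait",
                         "value"), "plots")
  df <- plots[plots$trait == trait & plots$environment == environment, ,
              drop = FALSE]
  if (nrow(df) == 0L) {
    abort(sprintf("No observations for trait '%s' in environment '%s'.",
                  trait, environment))
  }
  if (any(!is.finite(df$value))) {
    abort("Plot values must be finite.")
  }

  # average technical replicates within a genotype-block cell
  cells <- df |>
    dplyr::group_by(.data$genotype, .data$block) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  geno_levels <- sort(unique(cells$genotype))
  block_levels <- sort(unique(cells$block))
  gi <- match(cells$genotype, geno_levels)
  bi <- match(cells$block, block_levels)
  nG <- length(geno_levels)
  nB <- length(block_levels)

  # connectivity over the genotype-block bipartite graph
  parent <- uf_new(nG + nB)
  for (r in seq_len(nrow(cells))) {
    parent <- uf_union(parent, gi[r], nG + bi[r])
  }
  comp <- uf_components(parent)

  n_rep <- tabulate(gi, nbins = nG)
  out <- tibble::tibble(
    trait = trait, environment = environment, genotype = geno_levels,
    blue = NA_real_, se = NA_real_, n_rep = n_rep
  )

  for (cid in unique(comp[seq_len(nG)])) {
    g_in <- which(comp[seq_len(nG)] == cid)
    b_in <- which(comp[nG + seq_len(nB)] == cid)
    sub <- cells[gi %in% g_in & bi %in% b_in, , drop = FALSE]
    fit <- fit_component(sub, geno_levels[g_in], block_levels[b_in])
    idx <- match(geno_levels[g_in], out$genotype)
    out$blue[idx] <- fit$blue
    out$se[idx] <- fit$se
  }
  out$se[out$n_rep <= 1L] <- NA_real_
  if (anyNA(out$blue)) {
    warn(sprintf(
      "Environment '%s', trait '%s': %d genotype(s) not estimable; cells left missing.",
      environment, trait, sum(is.na(out$blue))))
  }
  out
}

# Least-squares adjusted means for one connected component.
fit_component <- function(cells, genos, blocks) {
  nG <- length(genos)
  nB <- length(blocks)
  if (nB == 1L || all(tabulate(match(cells$genotype, genos), nG) <= 1L)) {
    m <- tapply(cells$value, factor(cells$genotype, levels = genos), mean)
    return(list(blue = as.numeric(m), se = rep(NA_real_, nG)))
  }
  g <- factor(cells$genotype, levels = genos)
  b <- factor(cells$block, levels = blocks)
  X <- cbind(
    stats::model.matrix(~ 0 + g),
    stats::model.matrix(~ b)[, -1, drop = FALSE]
  )
  fit <- lm.fit(X, cells$value)
  beta <- fit$coefficients
  est_ok <- !is.na(beta)
  # contrast for genotype i: its cell mean at the reference block plus the
  # average of the block offsets (reference block contributes 0)
  L <- matrix(0, nG, ncol(X))
  L[, seq_len(nG)] <- diag(nG)
  if (nB > 1L) L[, nG + seq_len(nB - 1L)] <- 1 / nB
  blue <- rep(NA_real_, nG)
  se <- rep(NA_real_, nG)
  estimable <- apply(L, 1, function(l) all(est_ok[l != 0]))
  beta0 <- ifelse(est_ok, beta, 0)
  blue[estimable] <- as.numeric(L[estimable, , drop = FALSE] %*% beta0)

  rdf <- nrow(cells) - sum(est_ok)
  if (rdf > 0) {
    s2 <- sum(fit$residuals^2) / rdf
    XtX <- crossprod(X[, est_ok, drop = FALSE])
    Vi <- tryCatch(solve(XtX), error = function(e) NULL)
    if (!is.null(Vi)) {
      Lr <- L[, est_ok, drop = FALSE]
      se[estimable] <- sqrt(pmax(
        0, s2 * rowSums((Lr %*% Vi) * Lr)[estimable]))
    }
  }
  list(blue = blue, se = se)
}

#' Assemble BLUE tables for all traits and environments
#'
#' Runs [fit_environment_blues()] over every trait-environment combination
#' present in the plot table and stacks the results in long format, with a
#' stable ordering (trait, then environment, then genotype,
#' lexicographically).
#'
#' @inheritParams fit_environment_blues
#' @param traits Optional character vector restricting which traits to fit.
#' @param replicate_policy `"error"` (default) refuses duplicated
#'   `(genotype, environment, block, trait)` rows, listing the offenders;
#'   `"average"` treats them as technical replicates and averages them.
#' @return A long tibble: `trait`, `environment`, `genotype`, `blue`, `se`,
#'   `n_rep`. Empty input yields an empty tibble.
#' @export
fit_blues <- function(plots, traits = NULL,
                      replicate_policy = c("error", "average")) {
  check_columns(plots, c("genotype", "environment", "block", "trait",
                         "value"), "plots")
  replicate_policy <- match.arg(replicate_policy)
  if (!is.null(traits)) plots <- plots[plots$trait %in% traits, ,
                                       drop = FALSE]
  if (nrow(plots) == 0L) {
    return(tibble::tibble(trait = character(), environment = character(),
                          genotype = character(), blue = double(),
                          se = double(), n_rep = integer()))
  }
  key <- paste(plots$genotype, plots$environment, plots$block, plots$trait,
               sep = "\r")
  if (replicate_policy == "error" && anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0(
      "Duplicated plot rows (genotype/environment/block/trait): ",
      paste(head(gsub("\r", "/", dup), 5), collapse = "; "),
      if (length(dup) > 5) sprintf(" and %d more", length(dup) - 5),
      ". Use replicate_policy = \"average\" for technical replicates."))
  }
  combos <- unique(plots[, c("trait", "environment")])
  combos <- combos[order(combos$trait, combos$environment), , drop = FALSE]
  purrr::pmap(combos, function(trait, environment) {
    fit_environment_blues(plots, trait, environment)
  }) |>
    dplyr::bind_rows()
}

#' Write / read BLUE matrices
#'
#' `write_blues()` writes one genotype-by-environment value matrix TSV per
#' trait (`<trait>_blues.tsv`) with a companion `<trait>_se.tsv`;
#' `read_blues()` reads them back into the long format used throughout the
#' package. Values round-trip exactly (shortest round-trip decimal
#' serialization).
#'
#' @param blues Long BLUE tibble from [fit_blues()].
#' @param dir Directory for the TSV files.
#' @return `write_blues()` returns the written paths invisibly;
#'   `read_blues()` returns a long tibble `trait`, `environment`,
#'   `genotype`, `blue`, `se`.
#' @export
write_blues <- function(blues, dir) {
  check_columns(blues, c("trait", "environment", "genotype", "blue"),
                "blues")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tr in unique(blues$trait)) {
    sub <- blues[blues$trait == tr, , drop = FALSE]
    wide_v <- tidyr::pivot_wider(sub[, c("genotype", "environment", "blue")],
                                 names_from = "environment",
                                 values_from = "blue")
    f_v <- file.path(dir, paste0(tr, "_blues.tsv"))
    readr::write_tsv(fmt17(wide_v), f_v)
    paths <- c(paths, f_v)
    if ("se" %in% names(sub)) {
      wide_s <- tidyr::pivot_wider(sub[, c("genotype", "environment", "se")],
                                   names_from = "environment",
                                   values_from = "se")
      f_s <- file.path(dir, paste0(tr, "_se.tsv"))
      readr::write_tsv(fmt17(wide_s), f_s)
      paths <- c(paths, f_s)
    }
  }
  invisible(paths)
}

#' @rdname write_blues
#' @export
read_blues <- function(dir) {
  files <- list.files(dir, pattern = "_blues\\.tsv$", full.names = TRUE)
  if (!length(files)) abort(sprintf("No *_blues.tsv files found in %s.", dir))
  # values are parsed as text and converted by strtod so the 17-digit
  # serialization round-trips bit-exactly
  purrr::map(files, function(f) {
    tr <- sub("_blues\\.tsv$", "", basename(f))
    v <- readr::read_tsv(f, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    long <- tidyr::pivot_longer(v, -"genotype", names_to = "environment",
                                values_to = "blue")
    long$blue <- as.double(long$blue)
    f_s <- file.path(dirname(f), paste0(tr, "_se.tsv"))
    if (file.exists(f_s)) {
      s <- readr::read_tsv(f_s, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c")) |>
        tidyr::pivot_longer(-"genotype", names_to = "environment",
                            values_to = "se")
      s$se <- as.double(s$se)
      long <- dplyr::left_join(long, s, by = c("genotype", "environment"))
    } else {
      long$se <- NA_real_
    }
    long$trait <- tr
    long[, c("trait", "environment", "genotype", "blue", "se")]
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$blue))
}
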