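#' Specification for a synthetic connectome population
#'
#' Describes a population of structural-connectivity matrices containing two
#' planted architecture archetypes per sex. Archetype 1 and archetype 2 share
#' a common coarse base template; archetype 2 concentrates relatively more
#' weight on within-system edges (`contrast`) and carries a distinct fine
#' within-system edge texture. Subject-level variability is hierarchical:
#' lognormal noise on each system-pair weight (`sigma_coarse`, which sets the
#' intersubject similarity at the system level) and independent lognormal
#' noise on each fine edge (`sigma`).
#'
#' Defaults are calibrated so that the 7-system similarity structure matches
#' the reference population: mean Pearson correlation about 0.94 within an
#' architecture type and about 0.91 across types.
#'
#' @param n_per_group subjects per archetype per sex (>= 2).
#' @param sexes character vector of sex labels to generate.
#' @param fine fine [parcellation] (default 100 nodes / 7 systems).
#' @param contrast within- vs between-system contrast of archetype 2 (>= 0).
#' @param shape amplitude of archetype 2's between-system pattern deviations
#'   (see [default_templates()]); sets the across-type similarity drop.
#' @param sigma lognormal log-sd of per-fine-edge subject noise.
#' @param sigma_coarse lognormal log-sd of per-system-pair subject noise.
#' @param texture_sd log-sd of the fixed fine edge texture shared by all
#'   subjects of an archetype.
#' @param texture_cor correlation of the two archetypes' within-system edge
#'   textures (1 = identical texture, 0 = independent).
#' @param edge_mean_target mean unique edge weight after subject rescaling.
#' @param seed master seed; all randomness derives from it.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_per_group = 20L,
                            sexes = c("male", "female"),
                            fine = default_fine_parcellation(),
                            contrast = 0.45,
                            shape = 0.25,
                            sigma = 0.25,
                            sigma_coarse = 0.075,
                            texture_sd = 0.45,
                            texture_cor = 0.5,
                            edge_mean_target = 1e-4,
                            seed = 1L) {
  stopifnot(n_per_group >= 2L, contrast >= 0, shape >= 0, sigma >= 0,
            is.finite(sigma),
            sigma_coarse >= 0, texture_sd >= 0,
            texture_cor >= -1, texture_cor <= 1, edge_mean_target > 0)
  structure(list(n_per_group = as.integer(n_per_group), sexes = sexes,
                 fine = fine, coarse = induced_coarse_parcellation(fine),
                 contrast = contrast, shape = shape, sigma = sigma,
                 sigma_coarse = sigma_coarse, texture_sd = texture_sd,
                 texture_cor = texture_cor,
                 edge_mean_target = edge_mean_target,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# coarse base template: within-system weights on the diagonal, between-system
# weights off it. Values are a fixed synthetic archetype base with the usual
# SC features (within > between, heterogeneous between weights).
.base_within <- c(1.4, 1.5, 1.2, 1.1, 0.9, 1.2, 1.3)
.base_between <- c(0.55, 0.45, 0.30, 0.20, 0.35, 0.40,
                   0.50, 0.45, 0.18, 0.30, 0.35,
                   0.48, 0.22, 0.52, 0.38,
                   0.25, 0.46, 0.42,
                   0.24, 0.33,
                   0.60)
# per-entry modulation pattern for archetype 2's between-system weights
.between_pattern <- c(1.60, 0.40, 1.20, 0.80, 1.45, 0.55,
                      1.00, 1.50, 0.50, 1.30, 0.70,
                      1.40, 0.60, 1.10, 0.90,
                      1.55, 0.45, 1.25,
                      0.75, 1.35,
                      0.65)

coarse_template_base <- function(k = 7L) {
  B <- matrix(0, k, k)
  B[upper.tri(B)][order_upper_tri(k)] <- .base_between[seq_len(k * (k - 1) / 2)]
  B <- B + t(B)
  diag(B) <- .base_within[seq_len(k)]
  B
}

# indices mapping row-major upper-triangle order into R's column-major order
order_upper_tri <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  order(order(idx[, 1L], idx[, 2L]))
}

#' Coarse archetype templates
#'
#' Builds the two 7x7 coarse templates. Template 1 is the base; template 2
#' multiplies within-system (diagonal) entries by `(1 + contrast)` and each
#' between-system entry by `(1 - contrast * g)`, then rescales between-system
#' entries by one constant so both templates have exactly equal mean weight.
#' `g > 0` is a fixed per-entry pattern with mean about 1 whose spread is set
#' by `shape`: the mean effect of `contrast` shifts weight from between- to
#' within-system edges (invisible to Pearson similarity on between-system
#' edge vectors), while the `shape`-scaled deviations alter the relative
#' pattern of between-system weights (the component that lowers across-type
#' similarity). At `contrast = 0` the templates are identical.
#'
#' @param contrast nonnegative within/between concentration contrast; an
#'   error is raised if any between-system entry would be driven to zero or
#'   below.
#' @param shape relative amplitude of the per-entry pattern deviations.
#' @return List of two symmetric 7x7 matrices (`template1`, `template2`) with
#'   within-system weights on the diagonal.
#' @export
default_templates <- function(contrast, shape = 0.25) {
  stopifnot(contrast >= 0, shape >= 0)
  k <- 7L
  t1 <- coarse_template_base(k)
  g <- 1 + shape * (.between_pattern - 1)
  mult <- 1 - contrast * g
  if (any(mult <= 0))
    stop("parameter error: contrast too large, a between-system entry would be <= 0")
  t2 <- t1
  diag(t2) <- diag(t1) * (1 + contrast)
  bt <- t1[upper.tri(t1)] * mult[order_upper_tri(k)]
  # one constant on between entries so the unique-entry means match exactly
  target_between_sum <- sum(t1[upper.tri(t1)]) + sum(diag(t1)) - sum(diag(t2))
  if (target_between_sum <= 0)
    stop("parameter error: contrast too large to rebalance between-system weights")
  bt <- bt * (target_between_sum / sum(bt))
  t2[upper.tri(t2)] <- bt
  t2[lower.tri(t2)] <- t(t2)[lower.tri(t2)]
  list(template1 = t1, template2 = t2)
}

# internal structural seed: fixes the archetypes' fine edge texture, which is
# part of the archetype definition, not of subject-level randomness
.texture_seed <- 760341L

#' Fine-scale archetype templates
#'
#' Expands the coarse templates onto the fine parcellation: fine edge (i, j)
#' gets the coarse weight of its system pair times a fixed lognormal edge
#' texture `exp(texture_sd * z - texture_sd^2/2)`. The texture is shared
#' between archetypes on between-system edges; on within-system edges the two
#' archetypes' textures correlate at `texture_cor`, planting a within-system
#' shape difference between the archetypes.
#'
#' @param spec a [population_spec].
#' @return List of two n x n fine template matrices.
#' @export
archetype_fine_templates <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  tmpl <- default_templates(spec$contrast, spec$shape)
  fine <- spec$fine
  n <- fine$n_nodes
  sys_idx <- match(fine$systems, system_labels(fine))
  ne <- n * (n - 1L) / 2L
  zs <- with_seed(.texture_seed, list(shared = stats::rnorm(ne),
                                      a1 = stats::rnorm(ne),
                                      a2 = stats::rnorm(ne)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_sys <- sys_idx[idx[, 1L]] == sys_idx[idx[, 2L]]
  rho <- spec$texture_cor
  tau <- spec$texture_sd
  mix <- function(za) ifelse(same_sys,
                             rho * zs$shared + sqrt(1 - rho^2) * za,
                             zs$shared)
  build <- function(tm, z) {
    W <- matrix(0, n, n)
    base <- tm[cbind(sys_idx[idx[, 1L]], sys_idx[idx[, 2L]])]
    W[idx] <- base * exp(tau * z - tau^2 / 2)
    W + t(W)
  }
  list(template1 = build(tmpl$template1, mix(zs$a1)),
       template2 = build(tmpl$template2, mix(zs$a2)))
}

#' Draw one synthetic subject
#'
#' Applies subject-level noise to a fine archetype template: one lognormal
#' factor per system pair (including within-system pairs) and one per fine
#' edge, then rescales to the target mean edge weight.
#'
#' @param fine_template n x n fine template matrix.
#' @param spec a [population_spec].
#' @param seed integer seed for this subject's draws.
#' @param subject_id,sex subject metadata.
#' @return A [connectome].
#' @export
synthesize_subject <- function(fine_template, spec, seed,
                               subject_id = "subject", sex = "unspecified") {
  stopifnot(inherits(spec, "population_spec"))
  fine <- spec$fine
  n <- fine$n_nodes
  stopifnot(nrow(fine_template) == n)
  k <- length(system_labels(fine))
  sys_idx <- match(fine$systems, system_labels(fine))
  draws <- with_seed(seed, {
    eta <- matrix(0, k, k)
    eta[upper.tri(eta, diag = TRUE)] <-
      stats::rnorm(k * (k + 1) / 2, sd = spec$sigma_coarse)
    eta[lower.tri(eta)] <- t(eta)[lower.tri(eta)]
    eps <- stats::rnorm(n * (n - 1L) / 2L, sd = spec$sigma)
    list(eta = eta, eps = eps)
  })
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  W <- matrix(0, n, n)
  W[idx] <- fine_template[idx] *
    exp(draws$eta[cbind(sys_idx[idx[, 1L]], sys_idx[idx[, 2L]])]) *
    exp(draws$eps)
  W <- W + t(W)
  cm <- connectome(W, fine, subject_id = subject_id, sex = sex)
  scale_to_target_mean(cm, spec$edge_mean_target)
}

#' Generate a synthetic population with planted archetypes
#'
#' Produces `n_per_group` subjects per archetype per sex. Both sexes are
#' drawn from the same two archetypes. Per-subject seeds are derived from the
#' master seed and the subject index, so populations are reproducible and
#' extensible without reshuffling existing subjects.
#'
#' @param spec a [population_spec].
#' @return List with `subjects` (list of [connectome]) and `labels`
#'   (data.frame: subject_id, sex, archetype, group).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  templates <- archetype_fine_templates(spec)
  subjects <- list()
  labels <- list()
  idx <- 0L
  for (sex in spec$sexes) {
    for (arch in 1:2) {
      for (s in seq_len(spec$n_per_group)) {
        idx <- idx + 1L
        sid <- sprintf("%s_A%d_s%02d", sex, arch, s)
        cm <- synthesize_subject(templates[[arch]], spec,
                                 seed = derive_seed(spec$seed, idx),
                                 subject_id = sid, sex = sex)
        subjects[[sid]] <- cm
        labels[[sid]] <- data.frame(subject_id = sid, sex = sex,
                                    archetype = arch,
                                    group = paste0(sex, "_", arch))
      }
    }
  }
  list(subjects = unname(subjects),
       labels = do.call(rbind, c(unname(labels), list(make.row.names = FALSE))))
}

#' Write a population to disk
#'
#' Writes one dense TSV matrix per subject plus `manifest.csv`
#' (subject_id, sex, path), `labels.csv` (ground-truth archetypes) and the
#' parcellation map `parcellation.tsv`.
#'
#' @param pop result of [generate_population()].
#' @param outdir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_population <- function(pop, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(pop$subjects, function(cm) {
    p <- file.path(outdir, paste0(cm$subject_id, ".tsv"))
    write_sc_matrix(cm, p)
    p
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(pop$subjects, `[[`, character(1), "subject_id"),
    sex = vapply(pop$subjects, `[[`, character(1), "sex"),
    path = paths)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$labels, file.path(outdir, "labels.csv"),
                   row.names = FALSE)
  write_parcellation(pop$subjects[[1L]]$parcellation,
                     file.path(outdir, "parcellation.tsv"))
  invisible(file.path(outdir, "manifest.csv"))
}

#' Read a population from a manifest
#'
#' @param manifest_path CSV with columns subject_id, sex, path (relative
#'   paths resolved against the manifest directory).
#' @param parcellation a [parcellation] for the matrices.
#' @param header passed to [read_sc_matrix()].
#' @return List of [connectome] objects.
#' @export
read_population <- function(manifest_path, parcellation, header = FALSE) {
  man <- utils::read.csv(manifest_path, colClasses = "character")
  stopifnot(all(c("subject_id", "sex", "path") %in% names(man)))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_sc_matrix(p, parcellation, subject_id = man$subject_id[i],
                   sex = man$sex[i], header = header)
  })
}

#' Monte-Carlo similarity calibration of a population spec
#'
#' Measures the mean within-archetype and across-archetype Pearson
#' correlation of system-level (coarse) edge vectors for a given spec, the
#' quantity the generator's defaults are calibrated against.
#'
#' @param spec a [population_spec].
#' @return List with `within` and `across` mean correlations and the number
#'   of subject pairs behind each.
#' @export
population_calibration <- function(spec) {
  pop <- generate_population(spec)
  vecs <- vapply(pop$subjects,
                 function(cm) vectorize_edges(reparcellate(cm))$values,
                 numeric(length(system_labels(spec$fine)) *
                           (length(system_labels(spec$fine)) - 1) / 2))
  S <- stats::cor(vecs)
  arch <- pop$labels$archetype
  same <- outer(arch, arch, `==`) & upper.tri(S)
  diff <- outer(arch, arch, `!=`) & upper.tri(S)
  list(within = mean(S[same]), across = mean(S[diff]),
       n_within_pairs = sum(same), n_across_pairs = sum(diff))
}
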