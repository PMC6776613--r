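#' Expected mutant-allele frequency of a heterozygous mutation
#'
#' Under the diploid, copy-number-neutral read-fraction model a heterozygous
#' somatic mutation carried by a fraction `ccf` of tumor cells, in a sample
#' of purity `purity`, is expected at MAF
#' \eqn{\rho \cdot \mathrm{CCF} / 2}: half the tumor-cell alleles carry it,
#' and normal-cell reads dilute it proportionally.
#'
#' @param ccf cancer-cell fraction in `[0, 1]`.
#' @param purity tumor purity in `[0, 1]`.
#' @return expected MAF in `[0, 0.5]`.
#' @examples
#' expectedMaf(1, 1)      # 0.5: clonal het variant, pure tumor
#' expectedMaf(0.5, 0.8)  # 0.2
#' @export
expectedMaf <- function(ccf, purity) {
  stopifnot(all(ccf >= 0 & ccf <= 1), all(purity >= 0 & purity <= 1))
  purity * ccf / 2
}

#' Specify one clone for the paired-tumor simulator
#'
#' @param clone_id clone label.
#' @param ccf_pre,ccf_post cancer-cell fraction of the clone at the two
#'   timepoints, in `[0, 1]`.  The founder clone has both equal to 1;
#'   subclones are mutually exclusive (no nesting).
#' @param n_private number of somatic mutations private to this clone.
#' @return a `clone_spec` list.
#' @export
cloneSpec <- function(clone_id, ccf_pre, ccf_post, n_private) {
  stopifnot(ccf_pre >= 0, ccf_pre <= 1, ccf_post >= 0, ccf_post <= 1,
            n_private >= 0)
  structure(list(clone_id = as.character(clone_id),
                 ccf_pre = ccf_pre, ccf_post = ccf_post,
                 n_private = as.integer(n_private)),
            class = "clone_spec")
}

#' Configuration for the matched-pair tumor simulator
#'
#' Encodes the observational setting of a paired pre-/post-treatment
#' sequencing study: a founder clone plus mutually exclusive subclones whose
#' cancer-cell fractions may shift under treatment selection, purity
#' dilution at each timepoint, Poisson read depths with binomial
#' mutant-read sampling, and per-mutation effect classes.  Defaults model a
#' microdissected exome study: purity 0.8 at both timepoints (samples
#' admitted at >= 80% tumor cell nuclei), mean depth 100x.
#'
#' @param clones list of [cloneSpec()] entries; exactly one founder with
#'   `ccf_pre = ccf_post = 1`, and the non-founder CCFs must sum to at most
#'   1 at each timepoint.
#' @param purity_pre,purity_post tumor purity per timepoint, in (0, 1].
#' @param mean_depth mean sequencing depth (Poisson, truncated at >= 1).
#' @param n_germline number of heterozygous germline sites for
#'   [simulateGermlinePair()].
#' @param ns_fraction probability that a coding mutation is nonsynonymous
#'   (default 0.75, the typical exome nonsynonymous share of coding point
#'   mutations).
#' @param coding_fraction probability that a mutation is coding (default
#'   0.9, an exome-capture design).
#' @param post_private_mutations de novo mutations present only in the
#'   post-treatment sample, carried by a dedicated clone at
#'   `post_private_ccf`.
#' @param post_private_ccf CCF of the de novo clone at the post timepoint
#'   (default 0.2).
#' @param min_alt detection threshold: a variant is reported in a sample
#'   only when at least this many mutant reads are drawn (default 1).
#' @param seed integer seed; all randomness derives from it.
#' @return a validated `sim_config` list.
#' @export
simConfig <- function(clones = list(cloneSpec("founder", 1, 1, 100)),
                      purity_pre = 0.8, purity_post = 0.8,
                      mean_depth = 100, n_germline = 2000,
                      ns_fraction = 0.75, coding_fraction = 0.9,
                      post_private_mutations = 0L, post_private_ccf = 0.2,
                      min_alt = 1L, seed = 1L) {
  cfg <- list(clones = clones, purity_pre = purity_pre,
              purity_post = purity_post, mean_depth = mean_depth,
              n_germline = as.integer(n_germline),
              ns_fraction = ns_fraction,
              coding_fraction = coding_fraction,
              post_private_mutations = as.integer(post_private_mutations),
              post_private_ccf = post_private_ccf,
              min_alt = as.integer(min_alt), seed = as.integer(seed))
  .validateSimConfig(cfg)
  structure(cfg, class = "sim_config")
}

.validateSimConfig <- function(cfg) {
  bad <- character()
  if (!length(cfg$clones) || !all(vapply(cfg$clones, inherits, logical(1),
                                         "clone_spec")))
    bad <- c(bad, "clones (need a list of cloneSpec entries)")
  else {
    founder <- vapply(cfg$clones, function(cl)
      cl$ccf_pre == 1 && cl$ccf_post == 1, logical(1))
    if (sum(founder) != 1L)
      bad <- c(bad, "clones (need exactly one founder with ccf_pre = ccf_post = 1)")
    sub <- cfg$clones[!founder]
    if (length(sub)) {
      if (sum(vapply(sub, `[[`, numeric(1), "ccf_pre")) > 1 + 1e-9)
        bad <- c(bad, "clones (subclone ccf_pre values sum above 1)")
      if (sum(vapply(sub, `[[`, numeric(1), "ccf_post")) > 1 + 1e-9)
        bad <- c(bad, "clones (subclone ccf_post values sum above 1)")
    }
  }
  if (cfg$purity_pre <= 0 || cfg$purity_pre > 1) bad <- c(bad, "purity_pre")
  if (cfg$purity_post <= 0 || cfg$purity_post > 1) bad <- c(bad, "purity_post")
  if (cfg$mean_depth <= 0) bad <- c(bad, "mean_depth")
  if (cfg$n_germline < 0) bad <- c(bad, "n_germline")
  if (cfg$ns_fraction < 0 || cfg$ns_fraction > 1) bad <- c(bad, "ns_fraction")
  if (cfg$coding_fraction < 0 || cfg$coding_fraction > 1)
    bad <- c(bad, "coding_fraction")
  if (cfg$post_private_mutations < 0) bad <- c(bad, "post_private_mutations")
  if (cfg$post_private_ccf < 0 || cfg$post_private_ccf > 1)
    bad <- c(bad, "post_private_ccf")
  if (cfg$min_alt < 0) bad <- c(bad, "min_alt")
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  if (length(bad))
    stop("invalid simulator configuration field(s): ",
         paste(bad, collapse = "; "))
  invisible(TRUE)
}

# deterministic substream seed from a base seed and string labels, < 2^31
.substream <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(seed) * 2654435.0 + h * 97 + 12345) %% 2147483587)
}

# random mutation catalog: unique keys, bases, contexts, effect classes
.mutationCatalog <- function(n, coding_fraction, ns_fraction) {
  pos <- sample.int(100000000L, n)
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), character(1))
  p5 <- sample(.BASES, n, replace = TRUE)
  p3 <- sample(.BASES, n, replace = TRUE)
  coding <- runif(n) < coding_fraction
  nonsyn <- runif(n) < ns_fraction
  effect <- ifelse(coding, ifelse(nonsyn, "nonsynonymous", "synonymous"),
                   "noncoding")
  data.frame(chrom = sample(as.character(1:22), n, replace = TRUE),
             pos = pos, ref = ref, alt = alt,
             context = paste0(p5, ref, p3),
             effect_class = effect, stringsAsFactors = FALSE)
}

# depth/alt read draws for a block of mutations at a common expected MAF
.drawReads <- function(n, mean_depth, emaf) {
  depth <- pmax(1L, rpois(n, mean_depth))
  alt <- rbinom(n, depth, emaf)
  data.frame(depth = depth, alt = alt)
}

#' Simulate a matched PRE/POST tumor sample pair
#'
#' Generates two somatic variant tables from one underlying clonal
#' architecture.  Every mutation belongs to one clone; at each timepoint its
#' expected MAF is [expectedMaf()] of the clone's CCF and the sample's
#' purity, read depth is Poisson (truncated at 1) and the mutant-read count
#' binomial.  A mutation is detected in a sample only when at least
#' `min_alt` mutant reads are drawn, which produces the realistic partial
#' sharing of mutation complements between timepoints.  De novo
#' post-treatment mutations (if configured) join a dedicated clone absent
#' from the PRE sample.  Read draws are seeded per (sample, clone), so
#' enlarging one clone never perturbs another clone's reads.
#'
#' @param config a [simConfig()] object.
#' @return list with `pre` and `post` ([SampleVariants-class], purity
#'   metadata filled in), `truth` (data.frame: key columns, `clone_id`,
#'   `ccf_pre`, `ccf_post`, `expected_maf_pre`, `expected_maf_post`,
#'   `selected` — TRUE iff the clone's CCF rose, `effect_class`,
#'   `context`), and `contexts` (key + context table for
#'   [contextSpectrum()]).
#' @examples
#' cfg <- simConfig(clones = list(cloneSpec("founder", 1, 1, 50),
#'                                cloneSpec("sub1", 0.1, 0.6, 30)),
#'                  seed = 7)
#' sim <- simulatePair(cfg)
#' nVariants(sim$pre)
#' @export
simulatePair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validateSimConfig(config)
  clones <- config$clones
  if (config$post_private_mutations > 0L)
    clones <- c(clones, list(cloneSpec("post_private", 0,
                                       config$post_private_ccf,
                                       config$post_private_mutations)))
  n_total <- sum(vapply(clones, `[[`, integer(1), "n_private"))
  set.seed(.substream(config$seed, "catalog"))
  catalog <- .mutationCatalog(n_total, config$coding_fraction,
                              config$ns_fraction)
  clone_id <- rep(vapply(clones, `[[`, character(1), "clone_id"),
                  vapply(clones, `[[`, integer(1), "n_private"))
  ccf_pre <- rep(vapply(clones, `[[`, numeric(1), "ccf_pre"),
                 vapply(clones, `[[`, integer(1), "n_private"))
  ccf_post <- rep(vapply(clones, `[[`, numeric(1), "ccf_post"),
                  vapply(clones, `[[`, integer(1), "n_private"))
  truth <- cbind(catalog[c("chrom", "pos", "ref", "alt")],
                 data.frame(clone_id = clone_id,
                            ccf_pre = ccf_pre, ccf_post = ccf_post,
                            expected_maf_pre = expectedMaf(ccf_pre,
                                                           config$purity_pre),
                            expected_maf_post = expectedMaf(ccf_post,
                                                            config$purity_post),
                            selected = ccf_post > ccf_pre,
                            effect_class = catalog$effect_class,
                            context = catalog$context,
                            stringsAsFactors = FALSE))

  draw_sample <- function(which_tp) {
    emaf <- if (which_tp == "PRE") truth$expected_maf_pre else
      truth$expected_maf_post
    reads <- data.frame(depth = integer(n_total), alt = integer(n_total))
    for (cl in unique(clone_id)) {
      idx <- which(clone_id == cl)
      set.seed(.substream(config$seed, which_tp, cl))
      reads[idx, ] <- .drawReads(length(idx), config$mean_depth,
                                 emaf[idx][1])
    }
    detected <- reads$alt >= config$min_alt
    calls <- data.frame(chrom = truth$chrom, pos = truth$pos,
                        ref = truth$ref, alt = truth$alt,
                        ref_count = reads$depth - reads$alt,
                        alt_count = reads$alt,
                        effect_class = truth$effect_class,
                        stringsAsFactors = FALSE)[detected, , drop = FALSE]
    calls
  }

  pre <- SampleVariants("SIM_PRE", draw_sample("PRE"), timepoint = "PRE",
                        purity = config$purity_pre)
  post <- SampleVariants("SIM_POST", draw_sample("POST"), timepoint = "POST",
                         purity = config$purity_post)
  list(pre = pre, post = post, truth = truth,
       contexts = truth[c("chrom", "pos", "ref", "alt", "context")])
}

#' Simulate a matched germline pair (blood vs treated mucosa)
#'
#' Two samples drawn from the same `n_germline` germline variant sites with
#' independent Poisson depth and binomial read sampling per sample.  Sites
#' are heterozygous (expected MAF 0.5) or homozygous-alternate (expected
#' MAF 1) with probability `hom_fraction`; the het/hom mix supplies the
#' between-site MAF variance that makes two same-individual samples highly
#' concordant, as germline variant sets are.  Any apparent private variants
#' arise purely from detection dropout, mimicking a
#' blood-vs-irradiated-mucosa comparison in which treatment introduced no
#' mutations.  Optionally injects `n_private_b` genuinely private
#' heterozygous variants into the second sample for power experiments.
#'
#' @param config a [simConfig()] object (`n_germline`, `mean_depth`,
#'   `min_alt`, `seed` are used).
#' @param n_private_b number of injected second-sample-only variants
#'   (default 0).
#' @param hom_fraction probability a site is homozygous-alternate (default
#'   1/3, the familiar ~2:1 het:hom ratio of human genomes).
#' @return list with `bc` and `nrx` ([SampleVariants-class]).
#' @export
simulateGermlinePair <- function(config, n_private_b = 0L,
                                 hom_fraction = 1 / 3) {
  stopifnot(inherits(config, "sim_config"), config$n_germline >= 1,
            hom_fraction >= 0, hom_fraction <= 1)
  n <- config$n_germline
  n_private_b <- as.integer(n_private_b)
  set.seed(.substream(config$seed, "germline-catalog"))
  catalog <- .mutationCatalog(n + n_private_b, 0, 0)
  emaf <- ifelse(runif(n + n_private_b) < hom_fraction, 1, 0.5)
  emaf[n + seq_len(n_private_b)] <- 0.5     # injected variants are het
  shared_idx <- seq_len(n)
  make_sample <- function(sid, tp, idx) {
    set.seed(.substream(config$seed, "germline", sid))
    depth <- pmax(1L, rpois(length(idx), config$mean_depth))
    alt <- rbinom(length(idx), depth, emaf[idx])
    detected <- alt >= config$min_alt
    calls <- data.frame(chrom = catalog$chrom[idx], pos = catalog$pos[idx],
                        ref = catalog$ref[idx], alt = catalog$alt[idx],
                        ref_count = depth - alt, alt_count = alt,
                        effect_class = catalog$effect_class[idx],
                        stringsAsFactors = FALSE)[detected, , drop = FALSE]
    SampleVariants(sid, calls, timepoint = tp)
  }
  bc <- make_sample("SIM_BC", "BC", shared_idx)
  nrx <- make_sample("SIM_NRX", "Nrx",
                     c(shared_idx,
                       if (n_private_b > 0L) n + seq_len(n_private_b)))
  list(bc = bc, nrx = nrx)
}

#' Write simulator ground truth as JSON
#'
#' @param truth truth data.frame from [simulatePair()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
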