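# Synthetic pan-genome generator. The generator is first-class, tested code:
# it produces gene families with core/accessory/unique structure and a
# tunable Heaps exponent, coding sequences with controlled omega and Ks, a
# class-dependent codon-usage bias, and feature tables with planted
# monotone genome-size correlations — all with a known truth table.

#' Pan-genome structure model
#'
#' Describes how gene-family content is distributed over genomes. In `open`
#' mode, genome *i* (in a fixed generation order) introduces
#' `Poisson(heaps_kappa * i^(heaps_gamma - 1))` previously unseen accessory
#' families, and every previously seen accessory family recurs in genome *i*
#' with probability `m/i` where `m` is the number of genomes carrying it so
#' far. The recurrence rule makes genomes exchangeable, so rarefaction over
#' random genome orderings reproduces a Heaps-type power-law pan curve with
#' exponent close to `heaps_gamma`. In `closed` mode the family pool is
#' finite: all `core_families` are in every genome and each remaining pool
#' family is present in each genome independently with probability
#' `pool_presence`.
#'
#' @param n_genomes Number of genomes (>= 2). Default 56, a genome-collection
#'   size typical of single-genus probiotic studies.
#' @param core_families Number of families present in every genome (>= 1).
#' @param openness_mode `"open"` or `"closed"`.
#' @param heaps_kappa New-family scale of the open mode (> 0).
#' @param heaps_gamma Heaps exponent of the open mode, in (0, 1).
#' @param pool_size Total family pool of the closed mode
#'   (>= `core_families`).
#' @param pool_presence Per-genome presence probability of non-core pool
#'   families in closed mode.
#' @param family_length_codons Length model for family ancestors: a list with
#'   `mean` and `min` codon counts; lengths are `min + Poisson(mean - min)`.
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   model and seed.
#' @return An object of class `pangenome_model`.
#' @export
pangenome_model <- function(n_genomes = 56, core_families = 400,
                            openness_mode = c("open", "closed"),
                            heaps_kappa = 120, heaps_gamma = 0.3,
                            pool_size = 2 * core_families,
                            pool_presence = 0.5,
                            family_length_codons = list(mean = 150, min = 60),
                            seed = 1L) {
  openness_mode <- match.arg(openness_mode)
  if (n_genomes < 2) abort("n_genomes must be >= 2")
  if (core_families < 1) abort("core_families must be >= 1")
  if (openness_mode == "open" &&
      (heaps_gamma <= 0 || heaps_gamma >= 1)) {
    abort("heaps_gamma must lie in (0, 1) for an open model")
  }
  if (openness_mode == "open" && heaps_kappa <= 0) {
    abort("heaps_kappa must be positive")
  }
  if (openness_mode == "closed" && pool_size < core_families) {
    abort("pool_size must be >= core_families for a closed model")
  }
  if (family_length_codons$min < 10) abort("family_length_codons$min must be >= 10")
  structure(list(n_genomes = as.integer(n_genomes),
                 core_families = as.integer(core_families),
                 openness_mode = openness_mode,
                 heaps_kappa = heaps_kappa, heaps_gamma = heaps_gamma,
                 pool_size = as.integer(pool_size),
                 pool_presence = pool_presence,
                 family_length_codons = family_length_codons,
                 seed = as.integer(seed)),
            class = "pangenome_model")
}

#' Sequence-evolution model
#'
#' Controls how family ancestor sequences are generated and diverged.
#' Ancestor codons are drawn from a biased codon-usage distribution in which
#' each amino acid's preferred codon carries weight `exp(bias)`; core and
#' non-core families use `core_codon_bias` and `noncore_codon_bias`
#' respectively. Each genome's copy is then evolved by a per-codon
#' substitution process (uniform single-nucleotide proposals at rate
#' `3 * ks_target / 2` per codon per branch; synonymous proposals accepted,
#' nonsynonymous accepted with probability `omega_target`, stop-creating
#' proposals rejected), calibrated so that realized pairwise synonymous
#' divergence is close to `ks_target` and the realized Ka/Ks ratio close to
#' `omega_target`. Optionally, a per-genome synonymous codon-preference sweep
#' (controlled by `sweep_frac` and `genome_bias_sd`) re-draws a fraction of
#' each gene's codons within their synonymous family at a genome-specific
#' bias intensity, emulating strain-to-strain variation in translational
#' selection; it changes synonymous usage only, never the protein.
#'
#' @param omega_target True Ka/Ks (>= 0).
#' @param ks_target True pairwise synonymous divergence per synonymous site
#'   between any two genomes (>= 0, below synonymous saturation).
#' @param core_codon_bias,noncore_codon_bias Codon-usage skew (log-weight of
#'   the preferred codon) for core / non-core family ancestors.
#' @param genome_bias_sd Standard deviation of the per-genome bias intensity
#'   around its class value (0 disables genome-level variation).
#' @param sweep_frac Fraction of codons per gene copy re-drawn synonymously
#'   at the genome's bias intensity (0 disables the sweep).
#' @param seed Integer seed.
#' @return An object of class `evolution_model`.
#' @export
evolution_model <- function(omega_target = 0.2, ks_target = 0.5,
                            core_codon_bias = 1.0, noncore_codon_bias = 0.3,
                            genome_bias_sd = 0, sweep_frac = 0, seed = 1L) {
  if (omega_target < 0) abort("omega_target must be >= 0")
  if (ks_target < 0) abort("ks_target must be >= 0")
  # Jukes-Cantor correction must remain defined: the expected uncorrected
  # synonymous difference fraction 3/4 * (1 - exp(-4 ks / 3)) has to stay
  # clearly below the 3/4 saturation ceiling
  p_exp <- 3 / 4 * (1 - exp(-4 * ks_target / 3))
  if (p_exp >= 0.70) {
    abort(sprintf(paste0("ks_target = %g implies an expected synonymous ",
                         "difference fraction of %.3f, too close to the ",
                         "Jukes-Cantor saturation ceiling of 3/4"),
                  ks_target, p_exp))
  }
  if (sweep_frac < 0 || sweep_frac > 1) abort("sweep_frac must be in [0, 1]")
  structure(list(omega_target = omega_target, ks_target = ks_target,
                 core_codon_bias = core_codon_bias,
                 noncore_codon_bias = noncore_codon_bias,
                 genome_bias_sd = genome_bias_sd, sweep_frac = sweep_frac,
                 seed = as.integer(seed)),
            class = "evolution_model")
}

# codon-usage distribution over the 61 sense codons at bias b: amino acids
# uniform, preferred codon weight exp(b) within its synonymous family
codon_usage_dist <- function(b) {
  tb <- codon_tables()
  aa <- tb$aa[tb$sense]
  w <- ifelse(tb$preferred, exp(b), 1)
  p <- numeric(length(tb$sense))
  for (a in unique(aa)) {
    idx <- aa == a
    p[idx] <- w[idx] / sum(w[idx])
  }
  p / sum(p)
}

# sample an ancestor gene of L codons (ATG start, then biased sense codons)
sample_ancestor <- function(L, bias) {
  tb <- codon_tables()
  p <- codon_usage_dist(bias)
  idx <- sample.int(length(tb$sense), L - 1L, replace = TRUE, prob = p)
  c(match("ATG", tb$sense), idx)
}

# evolve a codon-index vector along one branch of length d (synonymous
# substitutions per synonymous site)
evolve_codons <- function(codons0, d, omega) {
  tb <- codon_tables()
  cpp_evolve_codons(codons0 - 1L, d, omega, tb$neigh, tb$syn) + 1L
}

# per-genome synonymous codon-preference sweep: re-draws each codon with
# probability frac from its synonymous family with preferred-codon weight
# exp(b); protein sequence is unchanged
synonymous_sweep <- function(codons, frac, b) {
  if (frac <= 0) return(codons)
  tb <- codon_tables()
  aa <- tb$aa[tb$sense]
  hit <- which(runif(length(codons)) < frac)
  for (i in hit) {
    fam <- which(aa == aa[codons[i]])
    w <- ifelse(tb$preferred[fam], exp(b), 1)
    codons[i] <- fam[sample.int(length(fam), 1L, prob = w / sum(w))]
  }
  codons
}

# presence structure: list(presence = families x genomes 0/1 matrix,
# class = per-family class)
presence_structure <- function(model) {
  N <- model$n_genomes
  core <- model$core_families
  if (model$openness_mode == "closed") {
    A <- model$pool_size - core
    pres <- matrix(0L, core + A, N)
    pres[seq_len(core), ] <- 1L
    if (A > 0) {
      pres[core + seq_len(A), ] <-
        matrix(rbinom(A * N, 1L, model$pool_presence), nrow = A)
      # a pool family absent everywhere is not part of the realized dataset
      keep <- rowSums(pres) > 0L
      pres <- pres[keep, , drop = FALSE]
    }
  } else {
    fams <- list()   # accessory family -> genome index vector
    m <- integer(0)  # current genome counts
    for (i in seq_len(N)) {
      if (length(m)) {
        inc <- which(runif(length(m)) < m / i)
        for (f in inc) fams[[f]] <- c(fams[[f]], i)
        m[inc] <- m[inc] + 1L
      }
      k_new <- rpois(1L, model$heaps_kappa * i^(model$heaps_gamma - 1))
      for (j in seq_len(k_new)) {
        fams[[length(fams) + 1L]] <- i
        m <- c(m, 1L)
      }
    }
    A <- length(fams)
    pres <- matrix(0L, core + A, N)
    pres[seq_len(core), ] <- 1L
    for (f in seq_len(A)) pres[core + f, fams[[f]]] <- 1L
  }
  n_occ <- rowSums(pres)
  cls <- ifelse(seq_len(nrow(pres)) <= core, "core",
                ifelse(n_occ == 1L, "unique", "accessory"))
  # an accessory family that happened to recur into every genome is core by
  # definition of the realized dataset
  cls[n_occ == N] <- "core"
  list(presence = pres, class = cls)
}

#' Generate a synthetic pan-genome dataset with known truth
#'
#' Draws the gene-family presence structure from `model`, then (optionally)
#' ancestor coding sequences and per-genome evolved copies from `evo`. Gene
#' identifiers are `"<genome>|<family>|1"`, so truth joins never need
#' heuristics.
#'
#' @param model A [pangenome_model()].
#' @param evo An [evolution_model()].
#' @param sequences Generate coding/protein sequences (`TRUE`) or only the
#'   presence structure and truth table (`FALSE`, much faster — sufficient
#'   for rarefaction studies).
#' @return A list of class `synthetic_pangenome` with elements
#'   \describe{
#'     \item{genes}{tibble: `gene_id`, `genome_id`, `family_id`, `class`,
#'       and (with `sequences = TRUE`) `cds`, `protein`.}
#'     \item{families}{truth tibble: `family_id`, `class`, `true_omega`,
#'       `length_codons`, `n_genomes`.}
#'     \item{model}{the structure model.}
#'     \item{evo}{the evolution model.}
#'   }
#' @export
#' @examples
#' ds <- generate_pangenome(
#'   pangenome_model(n_genomes = 4, core_families = 5, heaps_kappa = 3,
#'                   seed = 7),
#'   evolution_model(seed = 7),
#'   sequences = TRUE)
#' head(ds$genes)
generate_pangenome <- function(model, evo = evolution_model(),
                               sequences = TRUE) {
  stopifnot(inherits(model, "pangenome_model"), inherits(evo, "evolution_model"))
  tb <- codon_tables()
  with_seed(model$seed + 0L, {
    ps <- presence_structure(model)
  })
  nfam <- nrow(ps$presence)
  N <- model$n_genomes
  genome_ids <- sprintf("G%03d", seq_len(N))
  family_ids <- sprintf("F%05d", seq_len(nfam))
  flc <- model$family_length_codons

  with_seed(evo$seed + 1L, {
    lens <- flc$min + rpois(nfam, max(flc$mean - flc$min, 0))
    genes <- vector("list", N)
    if (sequences) {
      d_branch <- evo$ks_target / 2
      ancestors <- lapply(seq_len(nfam), function(f) {
        bias <- if (ps$class[f] == "core") evo$core_codon_bias else
          evo$noncore_codon_bias
        sample_ancestor(lens[f], bias)
      })
      genome_bias <- rnorm(N, 0, evo$genome_bias_sd)
      for (g in seq_len(N)) {
        fams <- which(ps$presence[, g] > 0L)
        cds <- character(length(fams))
        prot <- character(length(fams))
        for (k in seq_along(fams)) {
          f <- fams[k]
          cod <- evolve_codons(ancestors[[f]], d_branch, evo$omega_target)
          if (evo$sweep_frac > 0) {
            b_g <- (if (ps$class[f] == "core") evo$core_codon_bias else
              evo$noncore_codon_bias) + genome_bias[g]
            cod <- synonymous_sweep(cod, evo$sweep_frac, b_g)
          }
          cds[k] <- paste(tb$sense[cod], collapse = "")
          prot[k] <- translate_codons(tb$sense[cod])
        }
        genes[[g]] <- tibble(
          gene_id = paste(genome_ids[g], family_ids[fams], "1", sep = "|"),
          genome_id = genome_ids[g],
          family_id = family_ids[fams],
          class = ps$class[fams],
          cds = cds, protein = prot)
      }
    } else {
      for (g in seq_len(N)) {
        fams <- which(ps$presence[, g] > 0L)
        genes[[g]] <- tibble(
          gene_id = paste(genome_ids[g], family_ids[fams], "1", sep = "|"),
          genome_id = genome_ids[g],
          family_id = family_ids[fams],
          class = ps$class[fams])
      }
    }
  })
  structure(list(
    genes = bind_rows(genes),
    families = tibble(family_id = family_ids, class = ps$class,
                      true_omega = evo$omega_target,
                      length_codons = lens,
                      n_genomes = rowSums(ps$presence)),
    model = model, evo = evo),
    class = "synthetic_pangenome")
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits one protein FASTA and one CDS FASTA per genome, the truth tables as
#' TSV, and an echo of the generating models as a flat key-value config file.
#'
#' @param ds A `synthetic_pangenome` from [generate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return A tibble manifest of written files (invisibly).
#' @export
write_pangenome <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_pangenome"))
  if (!("cds" %in% names(ds$genes))) {
    abort("dataset was generated with sequences = FALSE; nothing to write")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (g in unique(ds$genes$genome_id)) {
    sub <- filter(ds$genes, .data$genome_id == g)
    pf <- file.path(dir, paste0(g, ".faa"))
    nf <- file.path(dir, paste0(g, ".fna"))
    write_fasta(tibble(gene_id = sub$gene_id, sequence = sub$protein), pf)
    write_fasta(tibble(gene_id = sub$gene_id, sequence = sub$cds), nf)
    files[[length(files) + 1L]] <- tibble(genome_id = g, protein = pf, cds = nf)
  }
  write_tsv_table(select(ds$genes, -dplyr::any_of(c("cds", "protein"))),
                  file.path(dir, "truth_genes.tsv"))
  write_tsv_table(ds$families, file.path(dir, "truth_families.tsv"))
  cfg <- c(
    sprintf("%s=%s", names(unclass(ds$model)),
            vapply(unclass(ds$model), function(x)
              paste(unlist(x), collapse = ","), character(1))),
    sprintf("%s=%s", names(unclass(ds$evo)),
            vapply(unclass(ds$evo), function(x)
              paste(unlist(x), collapse = ","), character(1))))
  writeLines(cfg, file.path(dir, "generator_config.txt"))
  invisible(bind_rows(files))
}

#' Simulate one diverged coding-sequence pair
#'
#' Draws a random ancestor of `n_codons` codons and evolves two independent
#' copies so that their expected synonymous divergence is `ks_target` and the
#' true Ka/Ks ratio is `omega_target`. Used for estimator-calibration
#' studies.
#'
#' @param n_codons Length in codons.
#' @param omega_target True Ka/Ks.
#' @param ks_target True pairwise synonymous divergence.
#' @param bias Codon-usage bias of the ancestor (see [evolution_model()]).
#' @return A tibble with one row per sequence (`seq_id`, `cds`).
#' @export
simulate_cds_pair <- function(n_codons, omega_target = 0.2, ks_target = 0.5,
                              bias = 0) {
  tb <- codon_tables()
  anc <- sample_ancestor(n_codons, bias)
  a <- evolve_codons(anc, ks_target / 2, omega_target)
  b <- evolve_codons(anc, ks_target / 2, omega_target)
  tibble(seq_id = c("seq_a", "seq_b"),
         cds = c(paste(tb$sense[a], collapse = ""),
                 paste(tb$sense[b], collapse = "")))
}

#' Generate a per-genome feature table with planted correlations
#'
#' Produces a `genome_size_bp` column plus one column per planted feature.
#' Features are generated through a Gaussian copula: a latent standard-normal
#' variable with Pearson correlation `2*sin(pi*rho/6)` to the genome-size
#' latent yields (asymptotically) the requested Spearman correlation; a
#' target of +/-1 degenerates to a pure strictly monotone transform of genome
#' size, and a target of 0 to an independent column.
#'
#' @param n_genomes Number of genomes.
#' @param planted Data frame with columns `feature` (name) and `rho` (signed
#'   Spearman target in `[-1, 1]`); an optional `direction` column
#'   (`"positive"`/`"negative"`) overrides the sign of `rho`.
#' @param seed Integer seed.
#' @return A tibble with columns `genome_id`, `genome_size_bp` and one
#'   numeric column per planted feature.
#' @export
#' @examples
#' generate_feature_table(
#'   8, tibble::tibble(feature = c("GI_count", "noise"), rho = c(0.8, 0)),
#'   seed = 1)
generate_feature_table <- function(n_genomes,
                                   planted = tibble(
                                     feature = c("GI_count", "GI_total_bp",
                                                 "IS_count", "prophage_count",
                                                 "prophage_total_bp"),
                                     rho = c(0.85, 0.85, 0.85, 0.6, 0.6)),
                                   seed = 1L) {
  planted <- as_tibble(planted)
  if (!all(c("feature", "rho") %in% names(planted))) {
    abort("planted must have columns `feature` and `rho`")
  }
  if ("direction" %in% names(planted)) {
    sgn <- ifelse(planted$direction == "negative", -1, 1)
    planted$rho <- sgn * abs(planted$rho)
  }
  if (any(abs(planted$rho) > 1)) abort("|rho| targets must be <= 1")
  with_seed(seed, {
    z0 <- rnorm(n_genomes)
    gs <- round(2.4e6 + 4e5 * z0)
    while (anyDuplicated(gs)) gs[duplicated(gs)] <- gs[duplicated(gs)] + 1L
    out <- tibble(genome_id = sprintf("G%03d", seq_len(n_genomes)),
                  genome_size_bp = gs)
    for (i in seq_len(nrow(planted))) {
      rho <- planted$rho[i]
      if (abs(rho) == 1) {
        # strictly monotone transform of genome size: Spearman exactly +/-1
        y <- sign(rho) * (gs / 1e5 + (gs / 1e6)^2)
      } else {
        r <- 2 * sin(pi * rho / 6)
        w <- r * z0 + sqrt(1 - r^2) * rnorm(n_genomes)
        y <- 20 * exp(0.8 * w)  # positive, right-skewed abundance scale
      }
      out[[planted$feature[i]]] <- y
    }
    out
  })
}
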