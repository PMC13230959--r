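## Synthetic-data generators.
##
## Every generator emits, alongside the simulated input, a truth table
## from which the expected answer of each downstream stage is computable.
## All randomness flows through the supplied seed; a fixed seed gives
## bit-identical output.

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Substitute each site independently with probability p, uniformly over
## the three alternative bases. Operates on a character vector.
.mutate_chars <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
    }
  }
  chars
}

## Branch substitution probability producing an expected *observed*
## pairwise divergence D when two lineages each take one branch from a
## common ancestor: identity after a branch chain is 1/4 + 3/4 * prod(f_i)
## with f = 1 - 4p/3, so a pairwise target D needs f_pair = 1 - 4D/3 and
## each of the two branches gets sqrt of the remaining factor.
.branch_prob <- function(f_branch) 3 * (1 - f_branch) / 4

#' Simulate a clade-structured bacterial population
#'
#' Generates core-genome sequences for \code{n_clades * strains_per_clade}
#' strains. Each clade carries a disjoint set of clade-private SNPs
#' (sensitivity and specificity exactly 1 by construction), the first
#' seven of which form a "diagnostic cluster" with primer-friendly
#' geometry inside one clade-specific core gene (two triplets of SNPs 12
#' bp apart, 230 bp between triplet starts, one interior probe SNP).
#' Remaining private SNPs are scattered over the clade's allotted genes.
#' Optional background noise substitutes sites independently at
#' \code{background_snp_rate} per site per strain. Each strain also draws
#' a Poisson number of mobile genetic elements whose expected count
#' depends on the habitat of its clade, with annotation flags mimicking
#' upstream plasmid/satellite/prophage/integrase calls.
#'
#' @param n_clades Number of clades.
#' @param strains_per_clade Strains per clade.
#' @param core_genes Number of core genes in the reference.
#' @param gene_length Gene length in bp.
#' @param clade_private_snps_per_clade Private SNPs planted per clade
#'   (>= 7; the first 7 form the diagnostic cluster).
#' @param background_snp_rate Per-site background substitution
#'   probability per strain.
#' @param habitat_assignment Optional character vector (length
#'   \code{n_clades}) of habitats in \{"oyster", "seawater"\}; default
#'   alternates starting with oyster.
#' @param mge_rate_oyster,mge_rate_seawater Expected MGE count per strain
#'   by habitat.
#' @param seed Integer seed.
#' @return List with elements \code{genomes} (named character vector),
#'   \code{reference} (ancestral sequence), \code{genes} (data frame of
#'   0-based half-open gene coordinates), \code{strains} (strain, clade,
#'   habitat), \code{snps} (truth table: clade, gene_id, position
#'   [0-based, genome-wide], ref, alt, in_cluster), and \code{mge}
#'   (annotation-flag rows per planted element).
#' @export
simulate_bacterial_population <- function(n_clades = 4,
                                          strains_per_clade = 10,
                                          core_genes = 40,
                                          gene_length = 900,
                                          clade_private_snps_per_clade = 12,
                                          background_snp_rate = 0,
                                          habitat_assignment = NULL,
                                          mge_rate_oyster = 6,
                                          mge_rate_seawater = 1,
                                          seed = 1) {
  stopifnot(n_clades >= 1, strains_per_clade >= 1, core_genes >= n_clades,
            gene_length >= 600, clade_private_snps_per_clade >= 7,
            background_snp_rate >= 0, mge_rate_oyster >= 0,
            mge_rate_seawater >= 0)
  if (is.null(habitat_assignment)) {
    habitat_assignment <- rep(c("oyster", "seawater"), length.out = n_clades)
  }
  stopifnot(length(habitat_assignment) == n_clades,
            all(habitat_assignment %in% c("oyster", "seawater")))
  set.seed(seed)
  gene_length <- as.integer(gene_length)
  glen <- core_genes * gene_length
  ref <- .split_chars(.rand_seq(glen))
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(core_genes)),
    start = (seq_len(core_genes) - 1L) * gene_length,
    end = seq_len(core_genes) * gene_length,
    stringsAsFactors = FALSE
  )
  # allot each clade a disjoint block of genes for its private SNPs
  genes_per_clade <- core_genes %/% n_clades
  bases <- c("A", "C", "G", "T")
  cluster_offsets <- c(0L, 12L, 24L, 120L, 230L, 242L, 254L)
  snp_rows <- list()
  for (cl in seq_len(n_clades)) {
    gene_block <- ((cl - 1L) * genes_per_clade + 1L):(cl * genes_per_clade)
    cluster_gene <- gene_block[1L]
    cluster_start <- genes$start[cluster_gene] + 100L
    pos <- cluster_start + cluster_offsets
    n_scatter <- clade_private_snps_per_clade - length(cluster_offsets)
    scatter_pool <- if (length(gene_block) > 1L) {
      genes$start[gene_block[2L]]:(genes$end[gene_block[length(gene_block)]] - 1L)
    } else {
      (cluster_start + 400L):(genes$end[gene_block[1L]] - 1L)
    }
    scatter_pool <- setdiff(scatter_pool, pos)
    if (n_scatter > 0) {
      pos <- c(pos, sort(sample(scatter_pool, n_scatter)))
    }
    in_cluster <- c(rep(TRUE, length(cluster_offsets)), rep(FALSE, max(0, n_scatter)))
    ref_al <- ref[pos + 1L]
    alt_al <- vapply(ref_al, function(x) sample(setdiff(bases, x), 1), "")
    gene_idx <- findInterval(pos, genes$start)
    snp_rows[[cl]] <- data.frame(
      clade = sprintf("V%d", cl),
      gene_id = genes$gene_id[gene_idx],
      position = pos,
      ref = ref_al,
      alt = unname(alt_al),
      in_cluster = in_cluster,
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, snp_rows)
  if (anyDuplicated(snps$position)) {
    stop("config error: overlapping planted SNP positions")
  }
  strains <- data.frame(
    strain = sprintf("V%d_s%02d", rep(seq_len(n_clades), each = strains_per_clade),
                     rep(seq_len(strains_per_clade), n_clades)),
    clade = sprintf("V%d", rep(seq_len(n_clades), each = strains_per_clade)),
    habitat = rep(habitat_assignment, each = strains_per_clade),
    stringsAsFactors = FALSE
  )
  genomes <- character(nrow(strains))
  names(genomes) <- strains$strain
  for (i in seq_len(nrow(strains))) {
    g <- ref
    mine <- snps[snps$clade == strains$clade[i], ]
    g[mine$position + 1L] <- mine$alt
    g <- .mutate_chars(g, background_snp_rate)
    genomes[i] <- paste(g, collapse = "")
  }
  # habitat-dependent MGE load with annotation flags per planted element
  rate <- ifelse(strains$habitat == "oyster", mge_rate_oyster, mge_rate_seawater)
  n_mge <- stats::rpois(nrow(strains), rate)
  classes <- c("plasmid", "prophage", "satellite")
  mge_rows <- list()
  for (i in seq_len(nrow(strains))) {
    if (n_mge[i] == 0) next
    cls <- sample(classes, n_mge[i], replace = TRUE, prob = c(0.45, 0.4, 0.15))
    mge_rows[[i]] <- data.frame(
      strain = strains$strain[i],
      rgp_id = sprintf("%s_rgp%02d", strains$strain[i], seq_len(n_mge[i])),
      class_truth = cls,
      plasmid_origin = cls == "plasmid",
      satellite_full_segment = cls == "satellite",
      viral_call = cls == "prophage",
      prophage_quality = ifelse(cls == "prophage", "high", "none"),
      viral_gene_count = ifelse(cls == "prophage", 1L + stats::rpois(n_mge[i], 3), 0L),
      integrase_present = cls %in% c("prophage", "satellite"),
      stringsAsFactors = FALSE
    )
  }
  mge <- if (length(mge_rows)) do.call(rbind, Filter(Negate(is.null), mge_rows)) else
    data.frame(strain = character(), rgp_id = character(),
               class_truth = character(), plasmid_origin = logical(),
               satellite_full_segment = logical(), viral_call = logical(),
               prophage_quality = character(), viral_gene_count = integer(),
               integrase_present = logical(), stringsAsFactors = FALSE)
  rownames(mge) <- NULL
  list(genomes = genomes, reference = paste(ref, collapse = ""),
       genes = genes, strains = strains, snps = snps, mge = mge)
}

#' Simulate a phage genome family with a planted taxonomy
#'
#' Genomes descend from a star phylogeny per species nested inside a star
#' per genus, with site-independent substitutions uniform over the three
#' alternative bases and no indels. Divergence parameters are expected
#' *observed pairwise* Hamming divergences (substitutions per site,
#' back-mutation corrected), so expected intergenomic similarities fall at
#' \code{100 * (1 - divergence)}: the defaults put same-species pairs near
#' 98, same-genus pairs near 85 and cross-genus pairs below 60, on the
#' correct sides of the 95 and 70 thresholds.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param genomes_per_species Genomes per species.
#' @param genome_length Genome length in bp.
#' @param within_species_divergence Expected pairwise divergence within a
#'   species; must be < 0.05.
#' @param within_genus_divergence Expected pairwise divergence between
#'   species of one genus; must lie in (0.05, 0.30).
#' @param between_genus_divergence Expected pairwise divergence between
#'   genera; must lie in (0.30, 0.74).
#' @param seed Integer seed.
#' @return List with \code{genomes} (named character vector) and
#'   \code{truth} (data frame genome_id, genus, species).
#' @export
simulate_phage_family <- function(n_genera = 3,
                                  species_per_genus = 2,
                                  genomes_per_species = 2,
                                  genome_length = 5000,
                                  within_species_divergence = 0.02,
                                  within_genus_divergence = 0.15,
                                  between_genus_divergence = 0.45,
                                  seed = 1) {
  d_ws <- within_species_divergence
  d_wg <- within_genus_divergence
  d_bg <- between_genus_divergence
  if (!(d_ws < 0.05 && d_wg > 0.05 && d_wg < 0.30 && d_bg > 0.30)) {
    stop("config error: divergence bands must satisfy ",
         "within_species < 0.05 < within_genus < 0.30 < between_genus")
  }
  if (d_bg >= 0.745) stop("config error: between_genus_divergence too close ",
                          "to the random-sequence limit (0.75)")
  set.seed(seed)
  f_ws <- sqrt(1 - 4 * d_ws / 3)
  f_wg <- sqrt((1 - 4 * d_wg / 3) / (1 - 4 * d_ws / 3))
  f_bg <- sqrt((1 - 4 * d_bg / 3) / (1 - 4 * d_wg / 3))
  p_ws <- .branch_prob(f_ws)   # species ancestor -> genome
  p_wg <- .branch_prob(f_wg)   # genus ancestor -> species ancestor
  p_bg <- .branch_prob(f_bg)   # family root -> genus ancestor
  root <- .split_chars(.rand_seq(genome_length))
  genomes <- character(0)
  truth <- list()
  for (g in seq_len(n_genera)) {
    genus_anc <- .mutate_chars(root, p_bg)
    for (s in seq_len(species_per_genus)) {
      sp_anc <- .mutate_chars(genus_anc, p_wg)
      for (m in seq_len(genomes_per_species)) {
        id <- sprintf("g%02d_s%02d_p%02d", g, s, m)
        genomes[id] <- paste(.mutate_chars(sp_anc, p_ws), collapse = "")
        truth[[id]] <- data.frame(genome_id = id,
                                  genus = sprintf("genus%02d", g),
                                  species = sprintf("genus%02d_sp%02d", g, s),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(genomes = genomes, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate a ddPCR abundance time series with raw droplet wells
#'
#' Per sampling date, replicate concentrations (copies/mL) are drawn
#' log-normally around a trend: constant, sinusoidal with
#' \code{seasonal_period}, or coupled at \code{coupling_lag} sampling
#' dates to a partner trend. Each replicate also yields one simulated
#' ddPCR well: the copies loaded into a 20 uL reaction are partitioned
#' into droplets and the number of positive droplets is drawn
#' Binomial(total, 1 - exp(-lambda)) with lambda the expected copies per
#' droplet, matching the Poisson model inverted by
#' \code{\link{absolute_quantification}}. Values below the limit of
#' quantification are flagged.
#'
#' @param n_dates Number of sampling dates (used when \code{dates} is
#'   NULL; spacing is then drawn unevenly at 1-4 days).
#' @param dates Optional strictly increasing ordinal day numbers.
#' @param replicates_per_date Replicates (e.g. individual oysters) per
#'   date; >= 2.
#' @param log10_mean Mean of the log10 concentration trend (copies/mL).
#' @param log10_sd Replicate-level log10 standard deviation.
#' @param seasonal_period Seasonal period in days, or NULL for none.
#' @param seasonal_amplitude Amplitude of the seasonal term (log10 units).
#' @param partner_trend Optional per-date log10 trend of a partner series
#'   (numeric, length \code{n_dates}) for lag coupling.
#' @param coupling_lag Lag in sampling dates applied to
#'   \code{partner_trend}, or NULL.
#' @param coupling_strength Mixing weight in \[0, 1\] of the lagged
#'   partner trend.
#' @param loq_copies_per_reaction Limit of quantification, copies per
#'   reaction.
#' @param sample_volume_ul Template volume per 20 uL reaction (converts
#'   copies/mL to copies/reaction).
#' @param total_droplets,droplet_volume_nl,reaction_volume_ul Droplet
#'   generator characteristics.
#' @param target_id Label for the simulated target.
#' @param seed Integer seed.
#' @return List with \code{series} (target_id, date, replicate, value
#'   [copies/mL], below_loq), \code{wells} (sample_id, date, replicate,
#'   total_droplets, positive_droplets, droplet_volume_nl,
#'   reaction_volume_ul), \code{trend} (date, log10_trend) and
#'   \code{loq_copies_per_ml}.
#' @export
simulate_ddpcr_series <- function(n_dates = 35,
                                  dates = NULL,
                                  replicates_per_date = 10,
                                  log10_mean = 3,
                                  log10_sd = 0.4,
                                  seasonal_period = NULL,
                                  seasonal_amplitude = 1,
                                  partner_trend = NULL,
                                  coupling_lag = NULL,
                                  coupling_strength = 0.9,
                                  loq_copies_per_reaction = 1,
                                  sample_volume_ul = 5,
                                  total_droplets = 15000,
                                  droplet_volume_nl = 0.85,
                                  reaction_volume_ul = 20,
                                  target_id = "target1",
                                  seed = 1) {
  set.seed(seed)
  if (is.null(dates)) {
    dates <- cumsum(c(180L, sample(1:4, n_dates - 1, replace = TRUE)))
  }
  n_dates <- length(dates)
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("config error: dates must be strictly increasing")
  }
  if (replicates_per_date < 2) stop("config error: need >= 2 replicates")
  if (!is.null(coupling_lag) && coupling_lag >= n_dates) {
    stop("config error: coupling_lag must be < number of dates")
  }
  trend <- rep(log10_mean, n_dates)
  if (!is.null(seasonal_period)) {
    trend <- trend + seasonal_amplitude * sin(2 * pi * dates / seasonal_period)
  }
  if (!is.null(partner_trend) && !is.null(coupling_lag)) {
    stopifnot(length(partner_trend) == n_dates,
              coupling_strength >= 0, coupling_strength <= 1)
    lagged <- rep(log10_mean, n_dates)
    idx <- seq_len(n_dates) - coupling_lag
    ok <- idx >= 1
    lagged[ok] <- partner_trend[idx[ok]]
    trend <- (1 - coupling_strength) * trend + coupling_strength * lagged
  }
  loq_ml <- loq_copies_per_reaction * 1000 / sample_volume_ul
  reps <- replicates_per_date
  value <- 10^(rep(trend, each = reps) +
                 stats::rnorm(n_dates * reps, 0, log10_sd))
  series <- data.frame(
    target_id = target_id,
    date = rep(dates, each = reps),
    replicate = rep(seq_len(reps), n_dates),
    value = value,
    below_loq = value < loq_ml,
    stringsAsFactors = FALSE
  )
  copies_per_reaction <- value * sample_volume_ul / 1000
  lambda <- copies_per_reaction * droplet_volume_nl / (reaction_volume_ul * 1000)
  positives <- stats::rbinom(length(lambda), total_droplets, 1 - exp(-lambda))
  wells <- data.frame(
    sample_id = sprintf("%s_d%03d_r%02d", target_id, series$date, series$replicate),
    date = series$date,
    replicate = series$replicate,
    total_droplets = total_droplets,
    positive_droplets = positives,
    droplet_volume_nl = droplet_volume_nl,
    reaction_volume_ul = reaction_volume_ul,
    stringsAsFactors = FALSE
  )
  list(series = series, wells = wells,
       trend = data.frame(date = dates, log10_trend = trend),
       loq_copies_per_ml = loq_ml)
}
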