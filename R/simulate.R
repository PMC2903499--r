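#' Simulate a heterogeneous-stock-like pedigree
#'
#' Generates `n_top_families` mutually unrelated top-level families.
#' Within each, the requested number of full-sib (nuclear) families is
#' spread over generations `1 .. generations-1`; first-generation parents
#' are new founders, later parents are drawn from the previous generation
#' of the same top-level family (topped up with immigrant founders when
#' too few candidates exist, so top-level families stay unrelated to each
#' other).  Full-sib family sizes are drawn from a normal truncated at 1.
#'
#' Uses the R random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param n_top_families number of unrelated top-level families.
#' @param n_fullsib_families total number of full-sib families.
#' @param mean_size,sd_size full-sib family size distribution.
#' @param generations number of generations (>= 2) including founders.
#' @return A [as_pedigree()] object.
#' @export
simulate_pedigree <- function(n_top_families = 85L,
                              n_fullsib_families = 172L,
                              mean_size = 11, sd_size = 8,
                              generations = 4L) {
  stopifnot(n_top_families >= 1L, n_fullsib_families >= 1L,
            mean_size > 0, sd_size >= 0, generations >= 2L)
  if (n_fullsib_families < n_top_families)
    stop("infeasible request: need at least one full-sib family per top-level family")
  nf <- rep(n_fullsib_families %/% n_top_families, n_top_families)
  extra <- n_fullsib_families %% n_top_families
  if (extra > 0L)
    nf[sample.int(n_top_families, extra)] <- nf[1L] + 1L
  id <- sire <- dam <- fam <- fsf <- character(0)
  gen <- integer(0)
  fs_counter <- 0L
  for (t in seq_len(n_top_families)) {
    tfam <- sprintf("fam%03d", t)
    members <- list()  # per generation: character vector of ids
    n_new_founder <- 0L
    new_founder <- function() {
      n_new_founder <<- n_new_founder + 1L
      fid <- sprintf("%s_F%02d", tfam, n_new_founder)
      id <<- c(id, fid); sire <<- c(sire, NA); dam <<- c(dam, NA)
      gen <<- c(gen, 0L); fam <<- c(fam, tfam); fsf <<- c(fsf, NA)
      members[[1L]] <<- c(members[[1L]], fid)
      fid
    }
    members[[1L]] <- character(0)
    gens_assigned <- rep(seq_len(generations - 1L), length.out = nf[t])
    used_pairs <- character(0)
    for (g in seq_len(generations - 1L)) {
      n_fams_g <- sum(gens_assigned == g)
      if (n_fams_g == 0L) next
      if (length(members) < g + 1L) members[[g + 1L]] <- character(0)
      for (q in seq_len(n_fams_g)) {
        cand <- if (g == 1L) character(0) else members[[g]]
        ## avoid full-sib matings, as breeding schemes do: try pairs from
        ## different nuclear families; otherwise outcross to a new founder
        pair <- NULL
        if (length(cand) >= 2L) {
          cand_fsf <- fsf[match(cand, id)]
          for (try in 1:20) {
            pr <- .resample(cand, 2L)
            key <- paste(sort(pr), collapse = "\r")
            sibs <- !anyNA(cand_fsf[match(pr, cand)]) &&
              cand_fsf[match(pr[1L], cand)] == cand_fsf[match(pr[2L], cand)]
            if (!key %in% used_pairs && !isTRUE(sibs)) { pair <- pr; break }
          }
        }
        if (is.null(pair)) {
          p1 <- if (length(cand) >= 1L) .resample(cand, 1L) else new_founder()
          p2 <- new_founder()
          pair <- c(p1, p2)
        }
        used_pairs <- c(used_pairs, paste(sort(pair), collapse = "\r"))
        fs_counter <- fs_counter + 1L
        fsname <- sprintf("fs%04d", fs_counter)
        size <- max(1L, as.integer(round(stats::rnorm(1L, mean_size, sd_size))))
        kids <- sprintf("%s_g%d_%s_%02d", tfam, g, fsname, seq_len(size))
        id <- c(id, kids)
        sire <- c(sire, rep(pair[1L], size))
        dam <- c(dam, rep(pair[2L], size))
        gen <- c(gen, rep(g, size))
        fam <- c(fam, rep(tfam, size))
        fsf <- c(fsf, rep(fsname, size))
        members[[g + 1L]] <- c(members[[g + 1L]], kids)
      }
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, generation = gen,
                         fullsib_family = fsf, family = fam,
                         stringsAsFactors = FALSE))
}

#' Assign animals to cages
#'
#' With probability `confounding` an animal is housed with full sibs
#' only; otherwise it joins a mixed pool shared across families.  Cage
#' sizes are drawn uniformly on `min_density .. max_density`; the realized
#' cage size is recorded as the cage-density covariate.  Animals without a
#' full-sib family (founders) always enter the pool.
#'
#' @param ped pedigree object.
#' @param min_density,max_density cage size bounds.
#' @param confounding probability in `[0, 1]` of family-pure housing.
#' @return Data frame `id`, `cage`, `cage_density` (rows in `ped` order).
#' @export
assign_cages <- function(ped, min_density = 2L, max_density = 7L,
                         confounding = 0.85) {
  stopifnot(confounding >= 0, confounding <= 1,
            min_density >= 1L, max_density >= min_density)
  n <- nrow(ped)
  confined <- !is.na(ped$fullsib_family) & stats::runif(n) < confounding
  cage <- rep(NA_character_, n)
  counter <- 0L
  new_label <- function() { counter <<- counter + 1L; sprintf("cage%04d", counter) }
  pool <- which(!confined)
  for (f in unique(ped$fullsib_family[confined])) {
    idx <- .resample(which(confined & !is.na(ped$fullsib_family) &
                           ped$fullsib_family == f))
    ch <- .cage_chunks(length(idx), min_density, max_density)
    at <- 0L
    labs <- character(0)
    for (s in ch$sizes) {
      labs <- c(labs, new_label())
      cage[idx[at + seq_len(s)]] <- labs[length(labs)]
      at <- at + s
    }
    if (ch$leftover > 0L) {
      ## keep a leftover sib with its family when a cage has room
      room <- ch$sizes < max_density
      if (length(labs) && any(room))
        cage[idx[length(idx)]] <- labs[which(room)[1L]]
      else pool <- c(pool, idx[length(idx)])
    }
  }
  pool <- .resample(pool)
  ch <- .cage_chunks(length(pool), min_density, max_density)
  at <- 0L
  for (s in ch$sizes) {
    cage[pool[at + seq_len(s)]] <- new_label()
    at <- at + s
  }
  if (ch$leftover > 0L) {
    ## merge a leftover singleton into the smallest existing cage
    last <- pool[length(pool)]
    tab <- table(cage)
    tab <- tab[tab < max_density]
    if (length(tab) == 0L) stop("cannot respect cage-density bounds")
    cage[last] <- names(tab)[which.min(tab)]
  }
  dens <- as.integer(table(cage)[cage])
  data.frame(id = ped$id, cage = cage, cage_density = dens,
             stringsAsFactors = FALSE)
}

.cage_chunks <- function(n, lo = 2L, hi = 7L) {
  sizes <- integer(0)
  while (n >= lo) {
    s <- .resample(seq.int(lo, hi), 1L)
    if (n - s > 0L && n - s < lo) s <- if (s < hi) s + (lo - (n - s)) else s - 1L
    s <- min(s, n, hi)
    sizes <- c(sizes, s)
    n <- n - s
  }
  list(sizes = sizes, leftover = n)
}

#' Simulate LD-structured SNP genotypes down a pedigree
#'
#' Founder gametes are drawn from a small pool of haplotypes (emulating
#' descent from a handful of progenitor strains): each pool haplotype is
#' a thresholded Gaussian first-order autoregression, giving adjacent-SNP
#' allele correlation about `adjacent_ld_rho` around allele frequencies
#' drawn from `Beta(maf_beta_params)` (clamped to `[0.05, 0.95]`).
#' Offspring gametes are parental haplotypes recombined with crossover
#' probability `recomb_fraction` between adjacent SNPs; chromosomes
#' segregate freely.  Dosages are haplotype sums; optional genotyping
#' dropout is sprinkled uniformly.
#'
#' @param ped pedigree object.
#' @param n_snps number of SNPs.
#' @param n_founder_haplotypes size of the founder haplotype pool (>= 2).
#' @param adjacent_ld_rho latent AR(1) correlation in `[0, 1)`.
#' @param recomb_fraction per-interval crossover probability.
#' @param maf_beta_params shape parameters of the allele-frequency Beta.
#' @param n_chrom number of chromosomes the SNPs are spread over.
#' @param missing_rate fraction of genotype calls set missing.
#' @return A [genotype_matrix()] object (samples in pedigree order).
#' @export
simulate_genotypes <- function(ped, n_snps = 2000L,
                               n_founder_haplotypes = 16L,
                               adjacent_ld_rho = 0.7,
                               recomb_fraction = 0.01,
                               maf_beta_params = c(1, 1),
                               n_chrom = 19L, missing_rate = 0) {
  stopifnot(n_founder_haplotypes >= 2L, adjacent_ld_rho >= 0,
            adjacent_ld_rho < 1, recomb_fraction >= 0, recomb_fraction <= 0.5)
  n_chrom <- min(n_chrom, n_snps)
  chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), seq_along),
                use.names = FALSE)
  newchrom <- c(TRUE, diff(chrom) != 0L)
  p <- pmin(0.95, pmax(0.05, stats::rbeta(n_snps, maf_beta_params[1L],
                                          maf_beta_params[2L])))
  thr <- stats::qnorm(p)
  pool <- matrix(0L, n_founder_haplotypes, n_snps)
  for (h in seq_len(n_founder_haplotypes)) {
    z <- numeric(n_snps)
    for (l in seq_len(n_snps)) {
      z[l] <- if (newchrom[l]) stats::rnorm(1L)
              else adjacent_ld_rho * z[l - 1L] +
                   sqrt(1 - adjacent_ld_rho^2) * stats::rnorm(1L)
    }
    pool[h, ] <- as.integer(z < thr)
  }
  n <- nrow(ped)
  ip <- match(ped$sire, ped$id)
  im <- match(ped$dam, ped$id)
  H1 <- matrix(0L, n, n_snps)
  H2 <- matrix(0L, n, n_snps)
  gamete <- function(h1, h2) {
    cross <- stats::runif(n_snps - 1L) < recomb_fraction
    start <- stats::runif(1L) < 0.5
    free <- stats::runif(n_snps) < 0.5  # used at chromosome starts
    which_h <- integer(n_snps)
    cur <- start
    for (l in seq_len(n_snps)) {
      if (newchrom[l]) cur <- free[l]
      else if (cross[l - 1L]) cur <- !cur
      which_h[l] <- cur
    }
    ifelse(which_h == 1L, h1, h2)
  }
  for (i in seq_len(n)) {
    if (is.na(ip[i])) H1[i, ] <- pool[sample.int(n_founder_haplotypes, 1L), ]
    else H1[i, ] <- gamete(H1[ip[i], ], H2[ip[i], ])
    if (is.na(im[i])) H2[i, ] <- pool[sample.int(n_founder_haplotypes, 1L), ]
    else H2[i, ] <- gamete(H1[im[i], ], H2[im[i], ])
  }
  d <- H1 + H2
  if (missing_rate > 0) {
    nm <- round(missing_rate * length(d))
    d[sample.int(length(d), nm)] <- NA_integer_
  }
  rownames(d) <- ped$id
  genotype_matrix(d, data.frame(snp = sprintf("snp%05d", seq_len(n_snps)),
                                chrom = sprintf("%02d", chrom), pos = pos,
                                allele1 = "A", allele2 = "B",
                                stringsAsFactors = FALSE))
}

#' Trait architecture specification
#'
#' Target variance ratios (fractions of `total_var`) for the generative
#' components of a simulated trait: polygenic additive background
#' (`h2_poly`), specific additive QTL (`q2_add`), dominance QTL (`d2`),
#' full-sib family environment (`f2`) and cage environment (`c2`); the
#' remainder is residual.  `cage_density_slope` enters as a fixed
#' covariate effect on top of the random components.
#'
#' @param h2_poly,q2_add,d2,f2,c2 non-negative ratios summing to < 1.
#' @param n_qtl_additive,n_qtl_dominant QTL counts.
#' @param cage_density_slope fixed regression on cage density.
#' @param total_var total variance of the random components.
#' @export
architecture_spec <- function(h2_poly = 0.25, q2_add = 0, d2 = 0,
                              f2 = 0.14, c2 = 0.02,
                              n_qtl_additive = 0L, n_qtl_dominant = 0L,
                              cage_density_slope = 0, total_var = 1) {
  ratios <- c(h2_poly = h2_poly, q2_add = q2_add, d2 = d2, f2 = f2, c2 = c2)
  stopifnot(all(ratios >= 0), sum(ratios) < 1, total_var > 0)
  if (q2_add > 0 && n_qtl_additive < 1L) stop("q2_add > 0 needs additive QTL")
  if (d2 > 0 && n_qtl_dominant < 1L) stop("d2 > 0 needs dominance QTL")
  structure(list(ratios = ratios, n_qtl_additive = as.integer(n_qtl_additive),
                 n_qtl_dominant = as.integer(n_qtl_dominant),
                 cage_density_slope = cage_density_slope,
                 total_var = total_var),
            class = "architecture_spec")
}

#' Simulate phenotypes with known architecture
#'
#' Generates `y = density*slope + f + c + sum_i L_i a_i + sum_i D_i d_i +
#' u_poly + e`: family and cage effects are i.i.d. normal per group,
#' the polygenic value follows the pedigree (gene flow with Mendelian
#' sampling), additive QTL act through dosage codes 0/1/2 and dominance
#' QTL through heterozygote indicators.  Each component vector is
#' rescaled after simulation so its realized population variance matches
#' the architecture target exactly, which makes parameter-recovery tests
#' well defined; the truth record stores the realized quantities.
#' Dominance QTL are drawn only from SNPs showing all three genotypes
#' with heterozygosity above 10%.
#'
#' @param geno genotypes for all pedigree members.
#' @param ped pedigree object.
#' @param cages result of [assign_cages()].
#' @param arch an [architecture_spec()].
#' @param polygenic basis of the polygenic background: `"markers"`
#'   (default) sums thousands of tiny additive effects over all SNPs, so
#'   aggregate-SNP relationship models are correctly specified and
#'   pedigree models approximately so; `"pedigree"` drops a normal
#'   effect down the pedigree (gene flow with Mendelian sampling,
#'   covariance exactly the numerator relationship matrix).
#' @param qtl_add_columns,qtl_dom_columns optional fixed SNP column
#'   indices for the QTL (defaults draw them at random; dominance
#'   columns must be dominance-eligible).
#' @param phenotyped `"nonfounders"` (default) leaves founders without
#'   trait records, as in an outbred breeding design where purchased
#'   breeders are not part of the experiment; `"all"` phenotypes every
#'   animal.  Component variances are realized over the phenotyped
#'   animals.
#' @return List with `phen` (data frame `id`, `y`, `cage`,
#'   `cage_density`, `fullsib_family`, `family`) and `truth` (QTL table,
#'   realized variances and ratios, per-animal genetic values and
#'   component vectors).
#' @export
simulate_phenotypes <- function(geno, ped, cages, arch,
                                polygenic = c("markers", "pedigree"),
                                qtl_add_columns = NULL,
                                qtl_dom_columns = NULL,
                                phenotyped = c("nonfounders", "all")) {
  polygenic <- match.arg(polygenic)
  phenotyped <- match.arg(phenotyped)
  stopifnot(inherits(arch, "architecture_spec"),
            identical(geno$ids, ped$id))
  n <- nrow(ped)
  tv <- arch$total_var
  r <- arch$ratios
  m <- ncol(geno$dosage)
  if (arch$n_qtl_additive + arch$n_qtl_dominant > m)
    stop("requested QTL count exceeds SNP count")
  has_y <- if (phenotyped == "all") rep(TRUE, n)
           else !(is.na(ped$sire) & is.na(ped$dam))
  if (sum(has_y) < 3L) stop("fewer than 3 phenotyped animals")
  rescale <- function(v, target) {
    if (target == 0) return(rep(0, n))
    s <- stats::var(v[has_y])
    if (s <= 0) stop("degenerate component: zero realized variance")
    v * sqrt(target * tv / s)
  }
  u <- numeric(n)
  if (r["h2_poly"] > 0) {
    if (polygenic == "markers") {
      ## infinitesimal marker model: tiny effects at every SNP
      Zc <- geno$dosage
      for (j in seq_len(ncol(Zc))) {
        cj <- Zc[, j]
        cj[is.na(cj)] <- mean(cj, na.rm = TRUE)
        Zc[, j] <- cj - mean(cj)
      }
      u <- drop(Zc %*% stats::rnorm(ncol(Zc))) / sqrt(ncol(Zc))
    } else {
      ## gene flow down the pedigree with Mendelian sampling
      ip <- match(ped$sire, ped$id); im <- match(ped$dam, ped$id)
      for (i in seq_len(n)) {
        u[i] <- if (is.na(ip[i]) || is.na(im[i])) stats::rnorm(1L)
                else 0.5 * (u[ip[i]] + u[im[i]]) +
                     stats::rnorm(1L, 0, sqrt(0.5))
      }
    }
    u <- rescale(u, r["h2_poly"])
  }
  ## family and cage
  f <- rep(0, n)
  if (r["f2"] > 0) {
    fam <- ped$fullsib_family
    lev <- unique(stats::na.omit(fam))
    eff <- stats::setNames(stats::rnorm(length(lev)), lev)
    f <- ifelse(is.na(fam), 0, eff[fam])
    f <- rescale(f, r["f2"])
  }
  cg <- rep(0, n)
  if (r["c2"] > 0) {
    lev <- unique(cages$cage)
    eff <- stats::setNames(stats::rnorm(length(lev)), lev)
    cg <- rescale(eff[cages$cage], r["c2"])
  }
  ## specific QTL
  pfreq <- colMeans(geno$dosage, na.rm = TRUE) / 2
  qtl <- data.frame(snp = character(0), index = integer(0),
                    add_effect = numeric(0), dom_effect = numeric(0))
  qa <- qd <- rep(0, n)
  imp <- function(col) { col[is.na(col)] <- mean(col, na.rm = TRUE); col }
  if (arch$n_qtl_additive > 0L) {
    ok <- which(pfreq >= 0.05 & pfreq <= 0.95)
    if (length(ok) < arch$n_qtl_additive) stop("not enough polymorphic SNPs")
    sel <- if (!is.null(qtl_add_columns)) {
      stopifnot(length(qtl_add_columns) == arch$n_qtl_additive)
      as.integer(qtl_add_columns)
    } else .resample(ok, arch$n_qtl_additive)
    Zq <- apply(geno$dosage[, sel, drop = FALSE], 2L, imp)
    cv <- apply(Zq[has_y, , drop = FALSE], 2L, stats::var)
    if (any(cv == 0))
      stop("QTL column(s) without genotype variation: ",
           paste(geno$map$snp[sel[cv == 0]], collapse = ", "))
    ## equal per-QTL variance shares, random sign, then a joint correction
    ## for LD between the QTL columns
    alpha <- sample(c(-1, 1), length(sel), replace = TRUE) *
      sqrt((r["q2_add"] * tv / length(sel)) / cv)
    qa <- drop(Zq %*% alpha)
    sc <- sqrt(r["q2_add"] * tv / stats::var(qa[has_y]))
    qa <- (qa - mean(qa[has_y])) * sc
    qtl <- rbind(qtl, data.frame(snp = geno$map$snp[sel], index = sel,
                                 add_effect = alpha * sc, dom_effect = 0))
  }
  if (arch$n_qtl_dominant > 0L) {
    elig <- which(apply(geno$dosage, 2L, dominance_eligible))
    if (length(elig) < arch$n_qtl_dominant)
      stop("not enough dominance-eligible SNPs (three genotypes, ",
           "heterozygosity > 10%)")
    sel <- if (!is.null(qtl_dom_columns)) {
      stopifnot(length(qtl_dom_columns) == arch$n_qtl_dominant,
                all(qtl_dom_columns %in% elig))
      as.integer(qtl_dom_columns)
    } else .resample(elig, arch$n_qtl_dominant)
    het <- apply(geno$dosage[, sel, drop = FALSE] == 1L, 2L,
                 function(col) imp(col * 1))
    delta <- sample(c(-1, 1), length(sel), replace = TRUE) *
      sqrt((r["d2"] * tv / length(sel)) /
             apply(het[has_y, , drop = FALSE], 2L, stats::var))
    qd <- drop(het %*% delta)
    sc <- sqrt(r["d2"] * tv / stats::var(qd[has_y]))
    qd <- (qd - mean(qd[has_y])) * sc
    qtl <- rbind(qtl, data.frame(snp = geno$map$snp[sel], index = sel,
                                 add_effect = 0, dom_effect = delta * sc))
  }
  e <- rescale(stats::rnorm(n), 1 - sum(r))
  y <- arch$cage_density_slope * cages$cage_density + f + cg + qa + qd + u + e
  y[!has_y] <- NA_real_
  realized <- c(h2_poly = stats::var(u[has_y]), q2_add = stats::var(qa[has_y]),
                d2 = stats::var(qd[has_y]), f2 = stats::var(f[has_y]),
                c2 = stats::var(cg[has_y]), e2 = stats::var(e[has_y])) / tv
  phen <- data.frame(id = ped$id, y = y, cage = cages$cage,
                     cage_density = cages$cage_density,
                     fullsib_family = ped$fullsib_family,
                     family = ped$family, stringsAsFactors = FALSE)
  list(phen = phen,
       truth = list(qtl = qtl, realized_ratios = realized,
                    total_var = tv,
                    genetic_value = u + qa + qd,
                    components = data.frame(id = ped$id, u = u, f = f,
                                            c = cg, qtl_add = qa,
                                            qtl_dom = qd, e = e)))
}

#' One-call synthetic heterogeneous-stock dataset
#'
#' Chains [simulate_pedigree()], [assign_cages()],
#' [simulate_genotypes()] and [simulate_phenotypes()] with shared
#' defaults that emulate a four-generation outbred mouse population:
#' 85 unrelated families, 172 full-sib families of mean size 11 (SD 8),
#' cages of 2-7 animals largely confounded with families.
#'
#' @param n_top_families,n_fullsib_families,mean_size,sd_size,generations
#'   pedigree structure, see [simulate_pedigree()].
#' @param n_snps,confounding,arch,seed remaining knobs.
#' @param ... passed to [simulate_genotypes()].
#' @return List `ped`, `cages`, `geno`, `phen`, `truth`.
#' @export
simulate_hs_dataset <- function(n_top_families = 85L,
                                n_fullsib_families = 172L,
                                mean_size = 11, sd_size = 8,
                                generations = 4L, n_snps = 2000L,
                                confounding = 0.85,
                                arch = architecture_spec(), seed = NULL,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigree(n_top_families, n_fullsib_families, mean_size,
                           sd_size, generations)
  cages <- assign_cages(ped, confounding = confounding)
  geno <- simulate_genotypes(ped, n_snps = n_snps, ...)
  sim <- simulate_phenotypes(geno, ped, cages, arch)
  list(ped = ped, cages = cages, geno = geno, phen = sim$phen,
       truth = sim$truth)
}
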