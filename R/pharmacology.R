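#' Fractional ion-channel block from the Hill equation
#'
#' Computes the fraction of an ionic current blocked at a given free drug
#' concentration, \code{block = C^h / (C^h + IC50^h)}.  An infinite IC50
#' encodes "no measurable block" and yields exactly 0.
#'
#' @param concentration Free drug concentration (uM), non-negative.  Vectorised.
#' @param ic50 Half-maximal inhibitory concentration (uM), positive or
#'   \code{Inf}.
#' @param hill Hill coefficient (dimensionless, positive).  Ignored when
#'   \code{ic50} is infinite.
#' @return Block fraction in \code{[0, 1)}.
#' @examples
#' hillBlock(0.002, 0.001, 0.6) # ~0.602, dofetilide IKr at free Cmax
#' hillBlock(1, 1, 2.5)         # 0.5 at C = IC50 for any Hill coefficient
#' @export
hillBlock <- function(concentration, ic50, hill) {
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentration must be non-negative")
  n <- max(length(concentration), length(ic50), length(hill))
  concentration <- rep_len(concentration, n)
  ic50 <- rep_len(ic50, n)
  hill <- rep_len(hill, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is.infinite(ic50[i])) {
      out[i] <- 0
      next
    }
    if (is.na(ic50[i]) || ic50[i] <= 0)
      stop("finite ic50 must be positive")
    if (is.na(hill[i]) || hill[i] <= 0)
      stop("hill coefficient must be positive when ic50 is finite")
    if (concentration[i] == 0) {
      out[i] <- 0
    } else {
      # (C/IC50)^h / ((C/IC50)^h + 1), computed on the log scale for the
      # extreme-ratio entries (blocks down to ~1e-42 must keep relative accuracy)
      lr <- hill[i] * (log(concentration[i]) - log(ic50[i]))
      out[i] <- if (lr > 0) 1 / (1 + exp(-lr)) else exp(lr) / (1 + exp(lr))
    }
  }
  out
}

#' Channel names used by the drug model
#' @return Character vector \code{c("INa", "INaL", "ICaL", "IKr")} in the
#'   order expected by the cell model's scaling vector.
#' @export
channelNames <- function() c("INa", "INaL", "ICaL", "IKr")

#' Construct a drug record
#'
#' @param name Drug identifier.
#' @param cmax_free_uM Free (unbound) therapeutic Cmax in uM, positive.
#' @param ic50_uM Named numeric of per-channel IC50s (uM); names must be a
#'   subset of \code{channelNames()}; \code{Inf} means no block.
#' @param hill Named numeric of per-channel Hill coefficients; \code{NA}
#'   allowed (and ignored) where the IC50 is infinite.
#' @return Object of class \code{drugRecord}.
#' @export
drugRecord <- function(name, cmax_free_uM, ic50_uM, hill) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(cmax_free_uM) || length(cmax_free_uM) != 1L ||
      is.na(cmax_free_uM) || cmax_free_uM <= 0)
    stop("cmax_free_uM must be a single positive number")
  bad <- setdiff(names(ic50_uM), channelNames())
  if (length(bad))
    stop("unknown channel key(s) in drug record '", name, "': ",
         paste(bad, collapse = ", "))
  full_ic50 <- stats::setNames(rep(Inf, 4), channelNames())
  full_hill <- stats::setNames(rep(NA_real_, 4), channelNames())
  full_ic50[names(ic50_uM)] <- ic50_uM
  full_hill[names(hill)] <- hill
  fin <- is.finite(full_ic50)
  if (any(full_ic50[fin] <= 0))
    stop("drug record '", name, "': finite IC50 values must be positive")
  if (any(is.na(full_hill[fin]) | full_hill[fin] <= 0))
    stop("drug record '", name,
         "': a positive Hill coefficient is required for every finite IC50")
  structure(list(name = name, cmax_free_uM = cmax_free_uM,
                 ic50_uM = full_ic50, hill = full_hill),
            class = "drugRecord")
}

#' @export
print.drugRecord <- function(x, ...) {
  cat("<drugRecord>", x$name, " (free Cmax ", x$cmax_free_uM, " uM)\n", sep = "")
  for (ch in channelNames()) {
    blk <- hillBlock(x$cmax_free_uM, x$ic50_uM[[ch]], x$hill[[ch]])
    cat(sprintf("  %-5s IC50 %10g uM  hill %5s  block@Cmax %.3g%%\n", ch,
                x$ic50_uM[[ch]],
                ifelse(is.na(x$hill[[ch]]), "-", format(x$hill[[ch]])),
                100 * blk))
  }
  invisible(x)
}

#' Per-channel conductance scalings for a drug at a Cmax multiple
#'
#' For each channel, \code{scaling = 1 - hillBlock(multiplier * Cmax, IC50,
#' hill)}; a scaling of 1 means no block.
#'
#' @param drug A \code{drugRecord} (or \code{NULL} for the drug-free control).
#' @param multiplier Non-negative Cmax multiplier (the screening protocol uses
#'   1, 5 and 10).
#' @return Named numeric scaling vector over \code{channelNames()}, values in
#'   \code{[0, 1]}, class \code{channelScalings}.
#' @export
drugScalings <- function(drug, multiplier = 1) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier < 0)
    stop("multiplier must be a single non-negative number")
  sc <- stats::setNames(rep(1, 4), channelNames())
  if (!is.null(drug)) {
    if (!inherits(drug, "drugRecord")) stop("drug must be a drugRecord or NULL")
    conc <- multiplier * drug$cmax_free_uM
    for (ch in channelNames())
      sc[[ch]] <- 1 - hillBlock(conc, drug$ic50_uM[[ch]], drug$hill[[ch]])
  }
  structure(sc, class = c("channelScalings", "numeric"))
}

#' @export
print.channelScalings <- function(x, ...) {
  y <- as.numeric(x)
  names(y) <- names(unclass(x))
  print(round(y, 3))
  invisible(x)
}

#' Load a drug-parameter table
#'
#' Reads a per-channel pharmacology table (CSV or JSON dialect with fields
#' \code{name, channel, cmax_free_uM, ic50_uM, hill}; the literal string
#' \code{"inf"} is an allowed IC50).  With no argument, the bundled table of
#' the seven CiPA reference drugs is loaded.
#'
#' @param path Path to a CSV (\code{.csv}) or JSON (\code{.json}) table;
#'   default: the bundled seven-drug table.
#' @return Named list of \code{drugRecord}s.
#' @export
loadDrugTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cipa_drug_table.csv",
                        package = "cardioscreen", mustWork = TRUE)
  if (!file.exists(path)) stop("drug table not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("name", "channel", "cmax_free_uM", "ic50_uM", "hill")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("drug table is missing column(s): ", paste(miss, collapse = ", "))
  ic50 <- suppressWarnings(ifelse(tolower(trimws(as.character(df$ic50_uM))) %in%
                                    c("inf", "infinity"),
                                  Inf, as.numeric(df$ic50_uM)))
  if (anyNA(ic50))
    stop("unparseable ic50_uM in row(s): ",
         paste(which(is.na(ic50)), collapse = ", "))
  bad <- which(is.finite(ic50) & ic50 <= 0)
  if (length(bad))
    stop("non-positive IC50 in row(s): ", paste(bad, collapse = ", "),
         " (drug ", paste(unique(df$name[bad]), collapse = ", "), ")")
  records <- list()
  for (nm in unique(df$name)) {
    rows <- df$name == nm
    cm <- unique(df$cmax_free_uM[rows])
    if (length(cm) != 1L)
      stop("drug '", nm, "' has inconsistent cmax_free_uM entries")
    records[[nm]] <- drugRecord(
      name = nm, cmax_free_uM = cm,
      ic50_uM = stats::setNames(ic50[rows], df$channel[rows]),
      hill = stats::setNames(as.numeric(df$hill[rows]), df$channel[rows]))
  }
  records
}

#' Write a drug-parameter table
#'
#' Inverse of \code{\link{loadDrugTable}}; round-trips exactly.
#'
#' @param records Named list of \code{drugRecord}s.
#' @param path Output path ending in \code{.csv} or \code{.json}.
#' @return \code{path}, invisibly.
#' @export
writeDrugTable <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(name = r$name, channel = channelNames(),
               cmax_free_uM = r$cmax_free_uM,
               ic50_uM = ifelse(is.infinite(r$ic50_uM), "inf",
                                format(r$ic50_uM, digits = 15)),
               hill = r$hill, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}
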