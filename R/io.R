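# Readers and writers for the standard formats the toolkit touches: FASTA,
# a coarse three-atom PDB dialect, dot-bracket secondary structure, contact
# map text, decoy pool directories and TSV reports. All writers use fixed
# number formats so output is byte-reproducible.

#' Read RNA sequences from a FASTA file
#'
#' Lowercase is accepted and T is normalized to U (with a message).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(character(0))
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    message("normalizing T to U on FASTA ingest")
    seqs <- chartr("T", "U", seqs)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("FASTA records with non-RNA symbols: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs character vector (names become record ids; unnamed records
#'   get `seq_<k>`).
#' @param path output path (parent directories are created).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  ids[ids == ""] <- sprintf("seq_%d", which(ids == ""))
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

glyco_n_name <- function(res) ifelse(res %in% c("A", "G"), "N9", "N1")

#' Read a coarse-grained structure from PDB
#'
#' Expects a single chain with P, C4' and the glycosidic N (N9 for purines,
#' N1 for pyrimidines) present for every residue; residues missing any of
#' the three atoms are reported by number.
#'
#' @param path PDB file.
#' @param chain optional chain id to select from a multi-chain file.
#' @return A `coarse_structure` (1-based residue order preserved).
#' @export
read_coarse_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("multi-chain PDB; select one with the chain argument (found: ",
           paste(chains, collapse = ", "), ")")
    }
  } else {
    at <- at[at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0L) stop("chain ", chain, " not found")
  }
  resnos <- unique(at$resno)
  L <- length(resnos)
  coords <- array(NA_real_, c(L, 3, 3))
  seq_chars <- character(L)
  missing <- c()
  for (r in seq_len(L)) {
    sub <- at[at$resno == resnos[r], , drop = FALSE]
    res <- sub$resid[1]
    res1 <- toupper(substr(res, nchar(res), nchar(res)))
    seq_chars[r] <- if (res1 %in% c("A", "C", "G", "U")) res1 else "A"
    want <- c("P", "C4'", glyco_n_name(seq_chars[r]))
    for (k in 1:3) {
      hit <- which(sub$elety == want[k])
      if (length(hit) == 0L && k == 3L) {
        hit <- which(sub$elety %in% c("N1", "N9"))
      }
      if (length(hit) == 0L) {
        missing <- c(missing, sprintf("%d(%s)", resnos[r], want[k]))
      } else {
        coords[r, k, ] <- as.numeric(sub[hit[1], c("x", "y", "z")])
      }
    }
  }
  if (length(missing)) {
    stop("residues missing required atoms: ", paste(missing, collapse = ", "))
  }
  coarse_structure(coords, paste(seq_chars, collapse = ""))
}

#' Write a coarse-grained structure as PDB
#'
#' Emits standard ATOM records (P, C4', N9/N1 chosen by residue type),
#' occupancy 1.00; coordinates keep the format's 3-decimal precision.
#'
#' @param s a `coarse_structure` (sequence defaults to all-A for naming).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_coarse_pdb <- function(s, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  L <- length(s)
  seq_chars <- if (is.null(s$sequence)) rep("A", L) else strsplit(s$sequence, "")[[1]]
  xyz <- c()
  elety <- c()
  resno <- c()
  resid <- c()
  for (r in seq_len(L)) {
    names3 <- c("P", "C4'", glyco_n_name(seq_chars[r]))
    for (k in 1:3) {
      xyz <- c(xyz, s$coords[r, k, ])
      elety <- c(elety, names3[k])
      resno <- c(resno, r)
      resid <- c(resid, seq_chars[r])
    }
  }
  bio3d::write.pdb(file = path, xyz = round(xyz, 3), elety = elety,
                   resno = resno, resid = resid,
                   chain = rep("A", length(elety)),
                   o = rep(1, length(elety)), b = rep(0, length(elety)))
  invisible(path)
}

#' Convert between pair lists and dot-bracket strings
#'
#' @param pairs two-column matrix of nested pairs.
#' @param L sequence length.
#' @return `pairs_to_dotbracket`: a dot-bracket string;
#'   `dotbracket_to_pairs`: a two-column integer matrix.
#' @export
pairs_to_dotbracket <- function(pairs, L) {
  chars <- rep(".", L)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @param db dot-bracket string (only `.`, `(`, `)` supported).
#' @export
dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c(".", "(", ")"))) {
    stop("unsupported dot-bracket symbols (pseudoknot layers not supported)")
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), 0L, 2L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unclosed '('")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Write / read a dot-bracket file
#'
#' Two lines: sequence (all-N when unknown) and structure.
#'
#' @param spec a `family_spec` (or list with `L` and `pairs`).
#' @param path file path.
#' @return `read_dotbracket` returns a list with `L` and `pairs`.
#' @export
write_dotbracket <- function(spec, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  sq <- if (!is.null(spec$sequence)) spec$sequence else
    strrep("N", spec$L)
  writeLines(c(sq, pairs_to_dotbracket(spec$pairs, spec$L)), path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("dot-bracket file needs sequence + structure")
  db <- lines[2]
  list(L = nchar(db), pairs = dotbracket_to_pairs(db), sequence = lines[1])
}

#' Write / read a contact map as whitespace-delimited text
#'
#' A comment header records the map metadata; values use a fixed scientific
#' format so files are byte-reproducible.
#'
#' @param cm a `contact_map`.
#' @param path file path.
#' @return `read_contact_map` returns the `contact_map`.
#' @export
write_contact_map <- function(cm, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# contact_map corrected=%s symmetrized=%s min_separation=%d",
                 cm$meta$corrected, cm$meta$symmetrized,
                 cm$meta$min_separation)
  rows <- apply(cm$values, 1L, function(r) {
    paste(sprintf("%.8e", r), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# contact_map", hdr)) stop("not a contact map file")
  get <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  vals <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  contact_map(vals, corrected = as.logical(get("corrected")),
              symmetrized = as.logical(get("symmetrized")),
              min_separation = as.integer(get("min_separation")))
}

#' Write a ranked contact list as TSV
#'
#' Three columns (i, j, score), 1-based indices.
#'
#' @param ranked data.frame from [rank_contacts()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_contacts_tsv <- function(ranked, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(i = ranked$i, j = ranked$j,
                    score = sprintf("%.8e", ranked$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a decoy pool directory
#'
#' Each decoy is stored as `decoy_XXX.pdb` plus an optional
#' `decoy_XXX.dist.rds` archive (distogram channels + manifest) and
#' `decoy_XXX.weights.tsv`.
#'
#' @param pool a `decoy_pool`.
#' @param dir directory (created if needed).
#' @return `read_decoy_pool` returns the `decoy_pool`.
#' @export
write_decoy_pool <- function(pool, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (n in seq_along(pool$decoys)) {
    d <- pool$decoys[[n]]
    stem <- file.path(dir, sprintf("decoy_%03d", n))
    write_coarse_pdb(d$structure, paste0(stem, ".pdb"))
    if (!is.null(d$distogram)) {
      saveRDS(list(manifest = list(format = "ribofold-distogram", version = 1L,
                                   L = d$distogram$L,
                                   channels = c("PP", "CC", "NN")),
                   channels = d$distogram$channels),
              paste0(stem, ".dist.rds"))
    }
    if (!is.null(d$weights)) {
      utils::write.table(d$weights, paste0(stem, ".weights.tsv"),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_decoy_pool
#' @export
read_decoy_pool <- function(dir) {
  pdbs <- sort(list.files(dir, pattern = "^decoy_[0-9]+\\.pdb$",
                          full.names = TRUE))
  if (length(pdbs) == 0L) stop("no decoy_*.pdb files in ", dir)
  decoys <- lapply(pdbs, function(p) {
    stem <- sub("\\.pdb$", "", p)
    st <- read_coarse_pdb(p)
    dg <- NULL
    if (file.exists(paste0(stem, ".dist.rds"))) {
      x <- readRDS(paste0(stem, ".dist.rds"))
      dg <- distogram(x$channels, x$manifest$L)
    }
    w <- NULL
    if (file.exists(paste0(stem, ".weights.tsv"))) {
      w <- as.matrix(utils::read.table(paste0(stem, ".weights.tsv"),
                                       sep = "\t"))
      dimnames(w) <- NULL
    }
    list(structure = st, distogram = dg, weights = w)
  })
  decoy_pool(decoys)
}

#' Write consensus energies as TSV
#'
#' @param models model list from [csor_pipeline()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_energies_tsv <- function(models, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(
    model = sprintf("model_%d", seq_along(models)),
    e2e = sprintf("%.6f", vapply(models, function(m) m$energy$e2e, 1)),
    dist = sprintf("%.6f", vapply(models, function(m) m$energy$dist, 1)),
    total = sprintf("%.6f", vapply(models, function(m) m$energy$total, 1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structure-evaluation report as TSV
#'
#' @param report one-row data.frame from [evaluate_structure()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  df <- as.data.frame(lapply(report, fmt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a base-pair annotation TSV
#'
#' Three columns: i, j, category in {wc, nwc, stack}.
#'
#' @param path TSV file.
#' @return data.frame with columns `i`, `j`, `category`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "category") %in% names(df)))
  if (any(!df$category %in% c("wc", "nwc", "stack"))) {
    stop("annotation categories must be wc, nwc or stack")
  }
  df
}
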