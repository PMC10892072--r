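#' Column-name mapping for substance tables
#'
#' Maps the canonical field names used throughout the package to the
#' header names of a particular CSV file. Only `id` and `smiles` are
#' mandatory; set any other entry to `NA` if the file lacks that column.
#'
#' @param id,name,smiles,potency_category,dpra_c_depletion,dpra_k_depletion,keratinosens_ec15,hclat_positive,sensis_class
#'   Header name in the file for each canonical field, or `NA` to skip.
#' @return Named character vector (canonical name -> file header).
#' @export
#' @examples
#' substance_schema(id = "CASRN", smiles = "SMILES")
substance_schema <- function(id = "id",
                             name = "name",
                             smiles = "smiles",
                             potency_category = "potency_category",
                             dpra_c_depletion = "dpra_c_depletion",
                             dpra_k_depletion = "dpra_k_depletion",
                             keratinosens_ec15 = "keratinosens_ec15",
                             hclat_positive = "hclat_positive",
                             sensis_class = "sensis_class") {
  out <- c(
    id = id, name = name, smiles = smiles,
    potency_category = potency_category,
    dpra_c_depletion = dpra_c_depletion,
    dpra_k_depletion = dpra_k_depletion,
    keratinosens_ec15 = keratinosens_ec15,
    hclat_positive = hclat_positive,
    sensis_class = sensis_class
  )
  storage.mode(out) <- "character"
  out
}

#' Read a substance table from CSV
#'
#' Reads a UTF-8 CSV with a header row into the canonical substance
#' tibble. Mapped columns are renamed to their canonical names and
#' typed; every unmapped column is kept as a numeric descriptor (or as
#' the precomputed embedding scalar if named accordingly). Cells that
#' cannot be parsed as the target type become missing values; the row
#' count is preserved.
#'
#' @param path Path to a CSV file.
#' @param schema A mapping from [substance_schema()].
#' @return A substance tibble with canonical columns first, then
#'   descriptor columns in file order.
#' @export
read_substances <- function(path, schema = substance_schema()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "skinsens_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  schema <- schema[!is.na(schema)]
  for (fld in c("id", "smiles")) {
    if (!fld %in% names(schema)) {
      abort(paste0("schema must map mandatory column '", fld, "'"),
            class = "skinsens_schema_error")
    }
  }
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mapped columns absent from file: ",
                 paste(missing_cols, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  canon <- tibble::tibble(.rows = nrow(raw))
  for (fld in names(schema)) canon[[fld]] <- raw[[schema[[fld]]]]
  desc_cols <- setdiff(names(raw), unname(schema))
  num_fields <- c("potency_category", "dpra_c_depletion", "dpra_k_depletion",
                  "keratinosens_ec15", "hclat_positive")
  for (fld in intersect(num_fields, names(canon))) {
    canon[[fld]] <- suppressWarnings(as.numeric(canon[[fld]]))
  }
  if ("potency_category" %in% names(canon)) {
    canon$potency_category <- as.integer(canon$potency_category)
  }
  if ("hclat_positive" %in% names(canon)) {
    bad <- !is.na(canon$hclat_positive) & !canon$hclat_positive %in% c(0, 1)
    if (any(bad)) {
      warn(paste0(sum(bad), " h-CLAT value(s) not 0/1 set to missing"))
      canon$hclat_positive[bad] <- NA_real_
    }
  }
  if ("sensis_class" %in% names(canon)) {
    cls <- tolower(trimws(canon$sensis_class))
    cls[cls == ""] <- NA_character_
    unknown <- !is.na(cls) & !cls %in% .sensis_levels
    if (any(unknown)) {
      warn(paste0("unrecognized SENS-IS class value(s) set to missing: ",
                  paste(unique(cls[unknown]), collapse = ", ")))
      cls[unknown] <- NA_character_
    }
    canon$sensis_class <- cls
  }
  for (dc in desc_cols) canon[[dc]] <- suppressWarnings(as.numeric(raw[[dc]]))
  validate_substances(canon)
  canon
}

#' Write a substance table to CSV
#'
#' Inverse of [read_substances()] under the default schema: writing and
#' re-reading is the identity on typed fields.
#'
#' @param data Substance tibble.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_substances <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Validate a substance table
#'
#' Checks the core invariants: unique non-missing ids, non-empty SMILES,
#' potency categories in 1..6 when present, positive EC1.5 and finite
#' depletions when present. Syntactically suspect SMILES raise a warning
#' only (validation is textual, not chemical).
#'
#' @param data Substance tibble.
#' @return `data`, invisibly; aborts on invariant violation.
#' @export
validate_substances <- function(data) {
  if (!all(c("id", "smiles") %in% names(data))) {
    abort("substance table needs 'id' and 'smiles' columns",
          class = "skinsens_schema_error")
  }
  if (anyNA(data$id) || any(trimws(as.character(data$id)) == "")) {
    abort("missing substance id", class = "skinsens_validation_error")
  }
  if (anyDuplicated(data$id)) {
    dups <- unique(data$id[duplicated(data$id)])
    abort(paste0("duplicate substance id(s): ", paste(dups, collapse = ", ")),
          class = "skinsens_validation_error")
  }
  if (anyNA(data$smiles) || any(nchar(trimws(data$smiles)) == 0)) {
    abort("empty SMILES string", class = "skinsens_validation_error")
  }
  bad_smiles <- !vapply(data$smiles, smiles_ok, logical(1))
  if (any(bad_smiles)) {
    warn(paste0("SMILES failed the syntactic check for id(s): ",
                paste(data$id[bad_smiles], collapse = ", ")))
  }
  if ("potency_category" %in% names(data)) {
    pc <- data$potency_category
    if (any(!is.na(pc) & !pc %in% 1:6)) {
      abort("potency_category outside 1..6", class = "skinsens_validation_error")
    }
  }
  if ("keratinosens_ec15" %in% names(data)) {
    ec <- data$keratinosens_ec15
    if (any(!is.na(ec) & ec <= 0)) {
      abort("keratinosens_ec15 must be positive", class = "skinsens_validation_error")
    }
  }
  for (col in c("dpra_c_depletion", "dpra_k_depletion")) {
    if (col %in% names(data) && any(is.infinite(data[[col]]), na.rm = TRUE)) {
      abort(paste0(col, " must be finite"), class = "skinsens_validation_error")
    }
  }
  invisible(data)
}

#' Syntactic SMILES check
#'
#' Verifies balanced parentheses and brackets and paired ring-closure
#' labels (digits and `%nn` pairs). Purely textual; no valence or
#' aromaticity model.
#'
#' @param smiles A single SMILES string.
#' @return `TRUE` if the string passes, else `FALSE`.
#' @export
#' @examples
#' smiles_ok("CC(=O)Oc1ccccc1C(=O)O")  # aspirin, TRUE
#' smiles_ok("C1CC")                   # unclosed ring, FALSE
smiles_ok <- function(smiles) {
  if (length(smiles) != 1 || is.na(smiles) || nchar(smiles) == 0) return(FALSE)
  chars <- strsplit(smiles, "")[[1]]
  depth_par <- 0L
  depth_brk <- 0L
  ring <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth_par <- depth_par + 1L
    else if (ch == ")") {
      depth_par <- depth_par - 1L
      if (depth_par < 0L) return(FALSE)
    } else if (ch == "[") {
      depth_brk <- depth_brk + 1L
      if (depth_brk > 1L) return(FALSE)
    } else if (ch == "]") {
      depth_brk <- depth_brk - 1L
      if (depth_brk < 0L) return(FALSE)
    } else if (depth_brk == 0L && grepl("[0-9]", ch)) {
      lab <- as.integer(ch)
      ring <- c(ring, lab)
    } else if (depth_brk == 0L && ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        return(FALSE)
      }
      ring <- c(ring, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (depth_par != 0L || depth_brk != 0L) return(FALSE)
  all(table(ring) %% 2L == 0L)
}

#' Derive stage labels from human potency categories
#'
#' Human evidence places each substance in one of six potency
#' categories. Categories 1-4 are sensitizers (1-2 strong, "1A"; 3-4
#' weak, "1B"); categories 5-6 are non-sensitizers, for which potency is
#' not applicable.
#'
#' @param potency_category Integer vector with values in 1..6.
#' @return A tibble with columns `hazard` (factor,
#'   non_sensitizer/sensitizer) and `potency` (factor,
#'   not_applicable/1B/1A), one row per input.
#' @export
#' @examples
#' derive_labels(c(1, 4, 5))
derive_labels <- function(potency_category) {
  pc <- potency_category
  if (length(pc) == 0) {
    return(tibble::tibble(
      hazard = factor(character(), levels = c("non_sensitizer", "sensitizer")),
      potency = factor(character(), levels = c("not_applicable", "1B", "1A"))
    ))
  }
  if (anyNA(pc) || !all(pc %in% 1:6)) {
    abort("potency_category must be in 1..6", class = "skinsens_domain_error")
  }
  hazard <- ifelse(pc <= 4, "sensitizer", "non_sensitizer")
  potency <- dplyr::case_when(
    pc <= 2 ~ "1A",
    pc <= 4 ~ "1B",
    TRUE ~ "not_applicable"
  )
  tibble::tibble(
    hazard = factor(hazard, levels = c("non_sensitizer", "sensitizer")),
    potency = factor(potency, levels = c("not_applicable", "1B", "1A"))
  )
}
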