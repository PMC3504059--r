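# Alphabets and ambiguity maps for the supported data types.
#
# DNA/RNA ambiguity resolutions come from Biostrings::IUPAC_CODE_MAP; amino
# acid ambiguities (B, Z, J, X) are spelled out here since Biostrings keeps
# them only as alphabet members, not as resolution sets.

.DATA_TYPES <- c("binary", "omc", "umc", "dna", "rna", "aa")

.AA_ONE <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
             "S","T","V","W","Y")

.AA_AMBIG <- list(
  B = c("D", "N"),
  Z = c("E", "Q"),
  J = c("I", "L"),
  X = .AA_ONE
)

# ambiguityMap: named list, names = ambiguity symbols, values = resolutions
ambiguityMap <- function(dataType) {
  switch(dataType,
    dna = {
      m <- Biostrings::IUPAC_CODE_MAP
      m <- m[nchar(m) > 1L]
      lapply(as.list(m), function(s) strsplit(s, "")[[1]])
    },
    rna = {
      m <- Biostrings::IUPAC_CODE_MAP
      m <- m[nchar(m) > 1L]
      out <- lapply(as.list(m), function(s) chartr("T", "U", strsplit(s, "")[[1]]))
      out
    },
    aa = .AA_AMBIG,
    list()
  )
}

# full set of admissible non-missing symbols for a data type
typeAlphabet <- function(dataType) {
  switch(dataType,
    binary = c("0", "1"),
    omc = as.character(0:9),
    umc = NULL,  # free alphabet, up to 25 symbols, validated at parse time
    dna = c("A", "C", "G", "T", names(ambiguityMap("dna"))),
    rna = c("A", "C", "G", "U", names(ambiguityMap("rna"))),
    aa = c(.AA_ONE, names(.AA_AMBIG)),
    stop("unknown data type: ", dataType)
  )
}

isSequenceType <- function(dataType) dataType %in% c("dna", "rna", "aa")

# symbols that resolve to more than one base state
ambiguitySymbols <- function(dataType) names(ambiguityMap(dataType))
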