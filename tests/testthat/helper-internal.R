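# short-hands for internal helpers used by the tests
with_seed <- ppscan:::with_seed
base_codes <- ppscan:::base_codes
cpp_scan_windows <- ppscan:::cpp_scan_windows

# adjusted Rand index between two labelings (used for recovery checks);
# mclust provides the reference implementation
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
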