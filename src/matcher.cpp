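#include <Rcpp.h>
#include <unordered_map>
#include <string>

using namespace Rcpp;

// Gapless scoring of an insert against one tile over their overlap.
// Mismatches are only tolerated at insert positions with quality >= qual_min;
// seed (first seed_len compared bases) and total mismatch budgets apply.
// Returns false as soon as the candidate cannot be valid.
static bool score_one(const char* ins, const char* qual, int ins_len,
                      const char* tile, int tile_len,
                      int seed_len, int max_seed_mm, int max_total_mm,
                      int qual_min, int total_cap,
                      int& seed_mm, int& total_mm) {
    const int L = ins_len < tile_len ? ins_len : tile_len;
    if (L == 0) return false;
    seed_mm = 0;
    total_mm = 0;
    for (int i = 0; i < L; ++i) {
        if (ins[i] != tile[i]) {
            if ((int)qual[i] - 33 < qual_min) return false;
            ++total_mm;
            if (i < seed_len) {
                ++seed_mm;
                if (seed_mm > max_seed_mm) return false;
            }
            if (total_mm > max_total_mm || total_mm > total_cap) return false;
        }
    }
    return true;
}

// Match many inserts against a tile library.
// status: 1 = matched, 2 = unmatched, 3 = ambiguous (tie at minimum mismatches).
// [[Rcpp::export]]
List cpp_match_inserts(CharacterVector inserts, CharacterVector quals,
                       CharacterVector tiles,
                       int seed_len, int max_seed_mm, int max_total_mm,
                       int qual_min) {
    const int n = inserts.size();
    const int m = tiles.size();

    std::vector<std::string> tile_seq(m);
    bool uniform = m > 0;
    size_t tlen0 = 0;
    for (int j = 0; j < m; ++j) {
        tile_seq[j] = as<std::string>(tiles[j]);
        if (j == 0) tlen0 = tile_seq[j].size();
        else if (tile_seq[j].size() != tlen0) uniform = false;
    }
    // exact-match fast path is only unambiguous when all tiles share one length
    std::unordered_map<std::string, int> exact;
    if (uniform) {
        exact.reserve(m * 2);
        for (int j = 0; j < m; ++j) exact[tile_seq[j]] = j;
    }

    IntegerVector status(n), tile_idx(n), seed_out(n), total_out(n);

    for (int r = 0; r < n; ++r) {
        const char* ins = CHAR(STRING_ELT(inserts, r));
        const char* qu = CHAR(STRING_ELT(quals, r));
        const int ins_len = LENGTH(STRING_ELT(inserts, r));

        if (uniform && (size_t)ins_len >= tlen0) {
            auto hit = exact.find(std::string(ins, tlen0));
            if (hit != exact.end()) {
                status[r] = 1; tile_idx[r] = hit->second + 1;
                seed_out[r] = 0; total_out[r] = 0;
                continue;
            }
        }

        int best = max_total_mm + 1, best_j = -1, best_seed = 0;
        bool tie = false;
        for (int j = 0; j < m; ++j) {
            int smm, tmm;
            if (score_one(ins, qu, ins_len, tile_seq[j].c_str(),
                          (int)tile_seq[j].size(), seed_len, max_seed_mm,
                          max_total_mm, qual_min, best, smm, tmm)) {
                if (tmm < best) {
                    best = tmm; best_j = j; best_seed = smm; tie = false;
                } else if (tmm == best) {
                    tie = true;
                }
            }
        }
        if (best_j < 0) {
            status[r] = 2; tile_idx[r] = NA_INTEGER;
            seed_out[r] = NA_INTEGER; total_out[r] = NA_INTEGER;
        } else if (tie) {
            status[r] = 3; tile_idx[r] = NA_INTEGER;
            seed_out[r] = NA_INTEGER; total_out[r] = best;
        } else {
            status[r] = 1; tile_idx[r] = best_j + 1;
            seed_out[r] = best_seed; total_out[r] = best;
        }
    }
    return List::create(_["status"] = status, _["tile"] = tile_idx,
                        _["seed_mm"] = seed_out, _["total_mm"] = total_out);
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Assemble simulated R1 reads: [UMI][adapter][insert +/- substitutions/indels],
// with per-base Phred qualities drawn from a truncated normal. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_reads(CharacterVector inserts, std::string adapter,
                        int umi_len, double error_rate, double indel_rate,
                        double qual_mean, double qual_sd,
                        int qual_lo, int qual_hi) {
    const int n = inserts.size();
    CharacterVector seq_out(n), qual_out(n), umi_out(n);
    std::string seq, qual;

    for (int r = 0; r < n; ++r) {
        const char* ins = CHAR(STRING_ELT(inserts, r));
        const int ins_len = LENGTH(STRING_ELT(inserts, r));

        seq.clear();
        std::string umi(umi_len, 'A');
        for (int i = 0; i < umi_len; ++i)
            umi[i] = BASES[(int)(unif_rand() * 4) & 3];
        seq += umi;
        seq += adapter;

        for (int i = 0; i < ins_len; ++i) {
            if (indel_rate > 0 && unif_rand() < indel_rate) {
                if (unif_rand() < 0.5) continue;            // deletion
                seq.push_back(BASES[(int)(unif_rand() * 4) & 3]); // insertion
            }
            char b = ins[i];
            if (error_rate > 0 && unif_rand() < error_rate) {
                char nb = b;
                while (nb == b) nb = BASES[(int)(unif_rand() * 4) & 3];
                b = nb;
            }
            seq.push_back(b);
        }

        qual.resize(seq.size());
        for (size_t i = 0; i < seq.size(); ++i) {
            int q = (int)std::lround(norm_rand() * qual_sd + qual_mean);
            if (q < qual_lo) q = qual_lo;
            if (q > qual_hi) q = qual_hi;
            qual[i] = (char)(q + 33);
        }

        seq_out[r] = seq;
        qual_out[r] = qual;
        umi_out[r] = umi;
    }
    return List::create(_["sequence"] = seq_out, _["quality"] = qual_out,
                        _["umi"] = umi_out);
}
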