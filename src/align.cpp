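#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Semi-global (fitting) alignment: the read is aligned end-to-end, the
// reference contributes an internal span with free leading/trailing overhangs.
// Costs follow the amplicon-mapping parameterisation: mismatch 2, inserted
// base 3, deleted base 3 (linear, per base). Ties prefer match/mismatch over
// gaps, then insertions over deletions, and the leftmost reference end point.

struct AlnResult {
    int cost;
    int ref_start;   // 0-based, inclusive
    int ref_end;     // 0-based, exclusive
    int n_match, n_mm, n_ins, n_del;
    std::string cigar;
};

static void rle_append(std::string &out, char op, int len) {
    out += std::to_string(len);
    out += op;
}

static AlnResult dp_align(const std::string &read, const std::string &ref,
                          int mm_cost, int ins_cost, int del_cost) {
    const int n = (int) read.size(), m = (int) ref.size();
    // dp[i][j]: min cost of aligning read[0..i) ending exactly at ref prefix j,
    // with the leading ref overhang free.  Stored row-major in one vector.
    std::vector<int> dp((size_t)(n + 1) * (m + 1));
    std::vector<unsigned char> bt((size_t)(n + 1) * (m + 1)); // 0 start,1 diag,2 ins(up),3 del(left)
    for (int j = 0; j <= m; ++j) { dp[j] = 0; bt[j] = 0; }
    for (int i = 1; i <= n; ++i) {
        dp[(size_t)i * (m + 1)] = i * ins_cost;
        bt[(size_t)i * (m + 1)] = 2;
        for (int j = 1; j <= m; ++j) {
            int diag = dp[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                       (read[i - 1] == ref[j - 1] ? 0 : mm_cost);
            int up   = dp[(size_t)(i - 1) * (m + 1) + j] + ins_cost;
            int left = dp[(size_t)i * (m + 1) + (j - 1)] + del_cost;
            int best = diag; unsigned char dir = 1;
            if (up < best)   { best = up;   dir = 2; }
            if (left < best) { best = left; dir = 3; }
            dp[(size_t)i * (m + 1) + j] = best;
            bt[(size_t)i * (m + 1) + j] = dir;
        }
    }
    // free trailing overhang: best end column in the last row (leftmost tie)
    int best_j = 0, best_cost = dp[(size_t)n * (m + 1)];
    for (int j = 1; j <= m; ++j) {
        int c = dp[(size_t)n * (m + 1) + j];
        if (c < best_cost) { best_cost = c; best_j = j; }
    }
    AlnResult res;
    res.cost = best_cost;
    res.ref_end = best_j;
    res.n_match = res.n_mm = res.n_ins = res.n_del = 0;
    // traceback
    std::string ops; // reversed op-per-column string
    int i = n, j = best_j;
    while (i > 0) {
        unsigned char dir = bt[(size_t)i * (m + 1) + j];
        if (dir == 1) {
            if (read[i - 1] == ref[j - 1]) { ops += '='; res.n_match++; }
            else                           { ops += 'X'; res.n_mm++; }
            --i; --j;
        } else if (dir == 2) {
            ops += 'I'; res.n_ins++; --i;
        } else {
            ops += 'D'; res.n_del++; --j;
        }
    }
    res.ref_start = j;
    // run-length encode reversed ops
    std::string cig;
    int k = (int) ops.size();
    int p = k - 1;
    while (p >= 0) {
        char op = ops[p];
        int len = 0;
        while (p >= 0 && ops[p] == op) { ++len; --p; }
        rle_append(cig, op, len);
    }
    res.cigar = cig;
    return res;
}

// Ungapped scan: best (leftmost) offset and its mismatch count, with early
// abort once a candidate offset exceeds the best mismatch count so far.
static void ungapped_best(const std::string &read, const std::string &ref,
                          int &best_off, int &best_mm) {
    const int n = (int) read.size(), m = (int) ref.size();
    best_off = -1; best_mm = n + 1;
    for (int off = 0; off + n <= m; ++off) {
        int mm = 0;
        const char *r = read.data(), *s = ref.data() + off;
        for (int i = 0; i < n; ++i) {
            if (r[i] != s[i] && ++mm >= best_mm) break;
        }
        if (mm < best_mm) { best_mm = mm; best_off = off; }
        if (best_mm == 0) break;
    }
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(CharacterVector reads, std::string ref,
                     int mm_cost, int ins_cost, int del_cost) {
    const int N = reads.size();
    IntegerVector cost(N), ref_start(N), ref_end(N);
    IntegerVector n_match(N), n_mm(N), n_ins(N), n_del(N);
    CharacterVector cigar(N);
    const int min_gap = ins_cost < del_cost ? ins_cost : del_cost;
    for (int r = 0; r < N; ++r) {
        std::string read = as<std::string>(reads[r]);
        const int n = (int) read.size();
        AlnResult res;
        bool done = false;
        if (n <= (int) ref.size()) {
            int off, mm;
            ungapped_best(read, ref, off, mm);
            int ungapped_cost = mm * mm_cost;
            // A gapped alignment costs at least min_gap; when the best
            // ungapped cost is <= min_gap it is provably optimal (ties
            // prefer mismatch over gap).
            if (ungapped_cost <= min_gap) {
                res.cost = ungapped_cost;
                res.ref_start = off;
                res.ref_end = off + n;
                res.n_match = n - mm;
                res.n_mm = mm;
                res.n_ins = res.n_del = 0;
                std::string cig;
                // per-column ops, run-length encoded
                int i = 0;
                while (i < n) {
                    bool eq = read[i] == ref[off + i];
                    int len = 0;
                    while (i < n && (read[i] == ref[off + i]) == eq) { ++len; ++i; }
                    rle_append(cig, eq ? '=' : 'X', len);
                }
                res.cigar = cig;
                done = true;
            }
        }
        if (!done) res = dp_align(read, ref, mm_cost, ins_cost, del_cost);
        cost[r] = res.cost;
        ref_start[r] = res.ref_start;
        ref_end[r] = res.ref_end;
        n_match[r] = res.n_match;
        n_mm[r] = res.n_mm;
        n_ins[r] = res.n_ins;
        n_del[r] = res.n_del;
        cigar[r] = res.cigar;
    }
    return List::create(_["cost"] = cost, _["ref_start"] = ref_start,
                        _["ref_end"] = ref_end, _["n_match"] = n_match,
                        _["n_mismatch"] = n_mm, _["n_ins"] = n_ins,
                        _["n_del"] = n_del, _["cigar"] = cigar);
}

static int base_row(char b) {
    switch (b) {
        case 'A': return 0; case 'C': return 1;
        case 'G': return 2; case 'T': return 3;
        default: return -1; // N etc: contributes no coverage
    }
}

// Fragment-aware pileup. Rows must be sorted by fragment then mate; positions
// covered by mate 1 of a fragment are not double-counted when mate 2 overlaps
// them. Deleted reference positions count as covered (a deletion call).
// [[Rcpp::export(name = ".pileup_cpp")]]
List pileup_cpp(int ref_len, IntegerVector frag, IntegerVector mate,
                CharacterVector seq, IntegerVector ref_start,
                CharacterVector cigar, LogicalVector pass, int n_frag) {
    IntegerMatrix counts(5, ref_len); // rows: A C G T del
    LogicalVector frag_indel(n_frag), frag_pass(n_frag);
    std::vector<int> covered((size_t) ref_len, -1); // fragment id marking
    const int N = frag.size();
    for (int r = 0; r < N; ++r) {
        if (!pass[r]) continue;
        int f = frag[r] - 1;
        if (f < 0 || f >= n_frag) stop("fragment index out of range");
        frag_pass[f] = true;
        std::string s = as<std::string>(seq[r]);
        std::string cig = as<std::string>(cigar[r]);
        bool first_mate = mate[r] == 1;
        int pos = ref_start[r]; // 0-based ref cursor
        int ri = 0;             // read cursor
        size_t ci = 0;
        while (ci < cig.size()) {
            int len = 0;
            while (ci < cig.size() && isdigit(cig[ci])) {
                len = len * 10 + (cig[ci] - '0');
                ++ci;
            }
            char op = cig[ci++];
            if (op == '=' || op == 'X' || op == 'M') {
                for (int k = 0; k < len; ++k) {
                    if (pos >= 0 && pos < ref_len) {
                        if (first_mate || covered[(size_t) pos] != f) {
                            int row = base_row(s[ri]);
                            if (row >= 0) {
                                counts(row, pos)++;
                                if (first_mate) covered[(size_t) pos] = f;
                            }
                        }
                    }
                    ++pos; ++ri;
                }
            } else if (op == 'D') {
                frag_indel[f] = true;
                for (int k = 0; k < len; ++k) {
                    if (pos >= 0 && pos < ref_len) {
                        if (first_mate || covered[(size_t) pos] != f) {
                            counts(4, pos)++;
                            if (first_mate) covered[(size_t) pos] = f;
                        }
                    }
                    ++pos;
                }
            } else if (op == 'I') {
                frag_indel[f] = true;
                ri += len;
            } else if (op == 'S') {
                ri += len;
            } else {
                stop("unsupported CIGAR op");
            }
        }
    }
    return List::create(_["counts"] = counts, _["frag_indel"] = frag_indel,
                        _["frag_pass"] = frag_pass);
}
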