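#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Alignment kernels shared by the assembler (local overlap scoring) and the
// read mapper (semi-global placement).  Scores are linear gap penalties; the
// traceback alphabet is M (aligned column, match or mismatch), I (read base
// absent from the target), D (target base absent from the read).

static inline void push_op(std::string &cig, char op, int len) {
    if (len <= 0) return;
    cig += std::to_string(len);
    cig += op;
}

// Smith-Waterman local alignment with traceback.  Returns the best score and
// the half-open spans of the aligned region on both sequences, plus the
// number of alignment columns.
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b,
                  double match, double mismatch, double gap) {
    const int m = a.size(), n = b.size();
    std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
    // traceback: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
    std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        cur[0] = 0.0;
        for (int j = 1; j <= n; ++j) {
            double diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
            double up = prev[j] + gap;
            double left = cur[j - 1] + gap;
            double s = diag; unsigned char t = 1;
            if (up > s) { s = up; t = 2; }
            if (left > s) { s = left; t = 3; }
            if (s <= 0.0) { s = 0.0; t = 0; }
            cur[j] = s;
            tb[(size_t)i * (n + 1) + j] = t;
            if (s > best) { best = s; bi = i; bj = j; }
        }
        std::swap(prev, cur);
    }
    int i = bi, j = bj, cols = 0;
    while (i > 0 && j > 0) {
        unsigned char t = tb[(size_t)i * (n + 1) + j];
        if (t == 0) break;
        ++cols;
        if (t == 1) { --i; --j; }
        else if (t == 2) { --i; }
        else { --j; }
    }
    return List::create(
        _["score"] = best,
        _["a_start"] = i, _["a_end"] = bi,
        _["b_start"] = j, _["b_end"] = bj,
        _["length"] = cols);
}

// Semi-global alignment: the pattern (read) is aligned end-to-end, the
// subject absorbs free leading/trailing gaps.  Returns the best score, the
// 0-based subject start, and a CIGAR over {M,I,D} covering the full pattern.
// [[Rcpp::export]]
List cpp_glocal_align(std::string pattern, std::string subject,
                      double match, double mismatch, double gap) {
    const int m = pattern.size(), n = subject.size();
    if (m == 0) stop("empty pattern");
    std::vector<double> prev(n + 1), cur(n + 1);
    std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
    for (int j = 0; j <= n; ++j) prev[j] = 0.0;      // free subject prefix
    for (int i = 1; i <= m; ++i) {
        cur[0] = i * gap;
        tb[(size_t)i * (n + 1)] = 2;
        for (int j = 1; j <= n; ++j) {
            double diag = prev[j - 1] +
                (pattern[i - 1] == subject[j - 1] ? match : mismatch);
            double up = prev[j] + gap;
            double left = cur[j - 1] + gap;
            double s = diag; unsigned char t = 1;
            if (up > s) { s = up; t = 2; }
            if (left > s) { s = left; t = 3; }
            cur[j] = s;
            tb[(size_t)i * (n + 1) + j] = t;
        }
        std::swap(prev, cur);
    }
    double best = prev[0]; int bj = 0;
    for (int j = 1; j <= n; ++j) if (prev[j] > best) { best = prev[j]; bj = j; }
    // traceback from (m, bj) to row 0
    std::string rev;
    int i = m, j = bj;
    while (i > 0) {
        unsigned char t = tb[(size_t)i * (n + 1) + j];
        if (t == 1) { rev += 'M'; --i; --j; }
        else if (t == 2) { rev += 'I'; --i; }
        else { rev += 'D'; --j; }
    }
    std::string cig;
    int run = 0; char op = 0;
    for (int k = (int)rev.size() - 1; k >= 0; --k) {
        if (rev[k] == op) ++run;
        else { push_op(cig, op, run); op = rev[k]; run = 1; }
    }
    push_op(cig, op, run);
    return List::create(
        _["score"] = best,
        _["subject_start"] = j,   // 0-based
        _["subject_end"] = bj,    // half-open
        _["cigar"] = cig);
}

static inline int base_index(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Accumulate pileup counts over a common target.  Matrix rows are target
// positions (0-based), columns A,C,G,T,N; deletions spanning a position add
// to N, insertions are skipped (they have no anchor).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector starts, CharacterVector cigars,
                         CharacterVector seqs, int target_len) {
    IntegerMatrix counts(target_len, 5);
    const int nr = starts.size();
    for (int r = 0; r < nr; ++r) {
        int ref = starts[r];           // 0-based
        std::string cig = as<std::string>(cigars[r]);
        std::string seq = as<std::string>(seqs[r]);
        size_t qpos = 0, p = 0;
        while (p < cig.size()) {
            int len = 0;
            while (p < cig.size() && isdigit(cig[p])) { len = len * 10 + (cig[p] - '0'); ++p; }
            char op = cig[p++];
            if (op == 'M') {
                for (int k = 0; k < len; ++k) {
                    if (ref >= 0 && ref < target_len && qpos < seq.size()) {
                        int bi = base_index(seq[qpos]);
                        if (bi >= 0) counts(ref, bi) += 1;
                    }
                    ++ref; ++qpos;
                }
            } else if (op == 'I' || op == 'S') {
                qpos += len;
            } else if (op == 'D') {
                for (int k = 0; k < len; ++k) {
                    if (ref >= 0 && ref < target_len) counts(ref, 4) += 1;
                    ++ref;
                }
            } else {
                stop("unsupported CIGAR op");
            }
        }
    }
    return counts;
}

// For each read base, the 0-based target position it is aligned to, or -1
// for insertions (no anchor).
// [[Rcpp::export]]
IntegerVector cpp_base_refpos(std::string cigar, int start, int readlen) {
    IntegerVector out(readlen, -1);
    int ref = start;
    size_t qpos = 0, p = 0;
    while (p < cigar.size()) {
        int len = 0;
        while (p < cigar.size() && isdigit(cigar[p])) { len = len * 10 + (cigar[p] - '0'); ++p; }
        char op = cigar[p++];
        if (op == 'M') {
            for (int k = 0; k < len; ++k) {
                if ((int)qpos < readlen) out[qpos] = ref;
                ++ref; ++qpos;
            }
        } else if (op == 'I' || op == 'S') {
            qpos += len;
        } else if (op == 'D') {
            ref += len;
        } else {
            stop("unsupported CIGAR op");
        }
    }
    return out;
}

// Row-wise ranking of allele counts: counts sorted descending with ties
// broken by the fixed allele order A<C<G<T<N.  Returns the sorted counts and
// the 1-based allele index occupying each rank.
// [[Rcpp::export]]
List cpp_rank_counts(IntegerMatrix counts) {
    const int n = counts.nrow(), k = counts.ncol();
    IntegerMatrix sorted(n, k), ord(n, k);
    for (int i = 0; i < n; ++i) {
        int idx[8];
        for (int j = 0; j < k; ++j) idx[j] = j;
        // stable insertion sort, descending by count
        for (int a = 1; a < k; ++a) {
            int v = idx[a], b = a - 1;
            while (b >= 0 && counts(i, idx[b]) < counts(i, v)) { idx[b + 1] = idx[b]; --b; }
            idx[b + 1] = v;
        }
        for (int j = 0; j < k; ++j) {
            sorted(i, j) = counts(i, idx[j]);
            ord(i, j) = idx[j] + 1;
        }
    }
    return List::create(_["sorted"] = sorted, _["order"] = ord);
}
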