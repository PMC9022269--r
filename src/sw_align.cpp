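#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman over DNA with full traceback.
//
// Gap cost convention: a length-L gap costs open + L * extend (the first
// gapped position pays open + extend). 'N' scores as a mismatch against
// everything, including another 'N', and never counts as an identity.
//
// Tie-breaking among equal-score optima: endpoints are collected in scan
// order (subject position, then query position), each is traced back, and
// the alignment with the smallest subject start, then smallest query start,
// then the largest number of alignment columns is returned. Endpoint
// collection is capped; for the near-duplicate-free inputs this package
// aligns, ties beyond the cap do not arise in practice.

static const int TB_CAP = 256;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s, double match, double mismatch,
                  double gap_open, double gap_extend) {
    const int n = (int)q.size();   // query length (rows)
    const int m = (int)s.size();   // subject length (cols)
    const double NEG = -1e18;
    const double open_ext = gap_open + gap_extend;

    // rolling score rows; full byte tracebacks
    std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
    std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
    // E[i][j] depends on (i, j-1): within current row. F[i][j] on (i-1, j).
    // traceback codes:
    //   tbH: 0 = local start, 1 = diagonal, 2 = from E (gap in query), 3 = from F (gap in subject)
    //   tbE: 0 = opened from H(i, j-1), 1 = extended from E(i, j-1)
    //   tbF: 0 = opened from H(i-1, j), 1 = extended from F(i-1, j)
    std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

    double best = 0.0;
    std::vector<std::pair<int, int> > ends; // (i, j) of tied best endpoints

    for (int i = 1; i <= n; ++i) {
        double Eval = NEG; // E[i][0]
        const char qc = q[(size_t)i - 1];
        for (int j = 1; j <= m; ++j) {
            const size_t idx = (size_t)i * (m + 1) + j;
            // E: gap in query (consume subject base j)
            double e_open = Hcur[j - 1] - open_ext;
            double e_ext = Eval - gap_extend;
            if (e_open >= e_ext) { Eval = e_open; tbE[idx] = 0; }
            else                 { Eval = e_ext;  tbE[idx] = 1; }
            // F: gap in subject (consume query base i)
            double f_open = Hprev[j] - open_ext;
            double f_ext = Fprev[j] - gap_extend;
            double Fval;
            if (f_open >= f_ext) { Fval = f_open; tbF[idx] = 0; }
            else                 { Fval = f_ext;  tbF[idx] = 1; }
            Fcur[j] = Fval;
            // H
            const char sc = s[(size_t)j - 1];
            const bool is_match = (qc == sc) && qc != 'N';
            double diag = Hprev[j - 1] + (is_match ? match : mismatch);
            double h = 0.0; unsigned char tb = 0;
            if (diag > h) { h = diag; tb = 1; }
            if (Eval > h) { h = Eval; tb = 2; }
            if (Fval > h) { h = Fval; tb = 3; }
            Hcur[j] = h; tbH[idx] = tb;
            if (h > best) {
                best = h;
                ends.clear();
                ends.push_back(std::make_pair(i, j));
            } else if (h == best && best > 0.0 && (int)ends.size() < TB_CAP) {
                ends.push_back(std::make_pair(i, j));
            }
        }
        std::swap(Hprev, Hcur);
        std::swap(Fprev, Fcur);
        Hcur[0] = 0.0;
    }

    if (best <= 0.0) {
        return List::create(_["score"] = 0.0, _["found"] = false);
    }

    // trace each candidate endpoint; pick smallest sstart, then qstart,
    // then longest alignment (most columns)
    int b_qs = -1, b_qe = -1, b_ss = -1, b_se = -1;
    int b_cols = -1, b_matches = -1, b_gapopen = -1, b_mismatch = -1;
    for (size_t c = 0; c < ends.size(); ++c) {
        int i = ends[c].first, j = ends[c].second;
        const int qe = i, se = j;
        int cols = 0, matches = 0, mism = 0, gapopens = 0;
        int state = 0; // 0 = H, 1 = E, 2 = F
        while (true) {
            const size_t idx = (size_t)i * (m + 1) + j;
            if (state == 0) {
                unsigned char tb = tbH[idx];
                if (tb == 0) break;
                if (tb == 1) {
                    ++cols;
                    const bool is_match = (q[(size_t)i - 1] == s[(size_t)j - 1]) && q[(size_t)i - 1] != 'N';
                    if (is_match) ++matches; else ++mism;
                    --i; --j;
                } else if (tb == 2) state = 1;
                else state = 2;
            } else if (state == 1) { // gap in query, consumes subject
                unsigned char tb = tbE[idx];
                ++cols; --j;
                if (tb == 0) { ++gapopens; state = 0; }
            } else {                 // gap in subject, consumes query
                unsigned char tb = tbF[idx];
                ++cols; --i;
                if (tb == 0) { ++gapopens; state = 0; }
            }
        }
        const int qs = i + 1, ss = j + 1;
        bool take = false;
        if (b_ss < 0) take = true;
        else if (ss < b_ss) take = true;
        else if (ss == b_ss && qs < b_qs) take = true;
        else if (ss == b_ss && qs == b_qs && cols > b_cols) take = true;
        if (take) {
            b_qs = qs; b_qe = qe; b_ss = ss; b_se = se;
            b_cols = cols; b_matches = matches; b_gapopen = gapopens;
            b_mismatch = mism;
        }
    }

    return List::create(
        _["score"] = best, _["found"] = true,
        _["qstart"] = b_qs, _["qend"] = b_qe,
        _["sstart"] = b_ss, _["send"] = b_se,
        _["length"] = b_cols, _["matches"] = b_matches,
        _["mismatch"] = b_mismatch, _["gapopen"] = b_gapopen);
}
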