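#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Soft-margin linear SVM solved in the dual by maximal-violating-pair SMO.
// Deterministic: no random initialisation, fixed pair-selection rule.
// Decision function: f(x) = sum_i alpha_i y_i <x_i, x> + b, predict +1 iff f >= 0.

namespace {

struct SmoFit {
    std::vector<double> alpha;
    double bias;
    int iterations;
    bool converged;
};

// K: dense n x n kernel (row-major or symmetric, indexing K[i*n+j]); y in {-1,+1}
SmoFit smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                 int n, double C, double tol, int max_iter)
{
    SmoFit out;
    out.alpha.assign(n, 0.0);
    std::vector<double>& a = out.alpha;
    std::vector<double> f(n, 0.0); // f_i = sum_j a_j y_j K_ij (bias excluded)
    const double bnd = 1e-12 * C;  // bound-set membership tolerance
    int it = 0;
    bool conv = false;

    for (it = 0; it < max_iter; ++it) {
        int i = -1, j = -1;
        double up_max = -1e300, low_min = 1e300;
        for (int t = 0; t < n; ++t) {
            const double g = (double)y[t] - f[t];
            const bool in_up  = (y[t] == 1 && a[t] < C - bnd) || (y[t] == -1 && a[t] > bnd);
            const bool in_low = (y[t] == -1 && a[t] < C - bnd) || (y[t] == 1 && a[t] > bnd);
            if (in_up && g > up_max)   { up_max = g; i = t; }
            if (in_low && g < low_min) { low_min = g; j = t; }
        }
        if (i < 0 || j < 0 || up_max - low_min <= tol) { conv = true; break; }

        const double Kii = K[(size_t)i * n + i];
        const double Kjj = K[(size_t)j * n + j];
        const double Kij = K[(size_t)i * n + j];
        double eta = Kii + Kjj - 2.0 * Kij;
        if (eta < 1e-12) eta = 1e-12;

        const double Ei = f[i] - (double)y[i];
        const double Ej = f[j] - (double)y[j];
        const double s = (double)y[i] * (double)y[j];

        double L, H;
        if (y[i] != y[j]) {
            L = std::max(0.0, a[j] - a[i]);
            H = std::min(C, C + a[j] - a[i]);
        } else {
            L = std::max(0.0, a[i] + a[j] - C);
            H = std::min(C, a[i] + a[j]);
        }

        double aj_new = a[j] + (double)y[j] * (Ei - Ej) / eta;
        if (aj_new < L) aj_new = L;
        else if (aj_new > H) aj_new = H;
        if (aj_new < bnd) aj_new = 0.0;           // snap to exact bounds so the
        else if (aj_new > C - bnd) aj_new = C;    // bound sets stay consistent
        const double daj = aj_new - a[j];
        if (std::fabs(daj) < 1e-14) { conv = true; break; } // clipped to a bound: no progress possible
        double ai_new = a[i] - s * daj;
        if (ai_new < bnd) ai_new = 0.0;
        else if (ai_new > C - bnd) ai_new = C;
        const double dai = ai_new - a[i];

        a[i] = ai_new;
        a[j] = aj_new;
        for (int t = 0; t < n; ++t)
            f[t] += dai * (double)y[i] * K[(size_t)i * n + t]
                  + daj * (double)y[j] * K[(size_t)j * n + t];
    }

    // bias from KKT conditions: average y - f over free support vectors,
    // else midpoint of the up/low bounds
    const double eps = 1e-8 * C;
    double sum = 0.0; int n_free = 0;
    for (int t = 0; t < n; ++t) {
        if (a[t] > eps && a[t] < C - eps) { sum += (double)y[t] - f[t]; ++n_free; }
    }
    if (n_free > 0) {
        out.bias = sum / n_free;
    } else {
        double up_max = -1e300, low_min = 1e300;
        for (int t = 0; t < n; ++t) {
            const double g = (double)y[t] - f[t];
            const bool in_up  = (y[t] == 1 && a[t] < C) || (y[t] == -1 && a[t] > 0.0);
            const bool in_low = (y[t] == -1 && a[t] < C) || (y[t] == 1 && a[t] > 0.0);
            if (in_up && g > up_max) up_max = g;
            if (in_low && g < low_min) low_min = g;
        }
        if (up_max < -1e299) up_max = low_min;
        if (low_min > 1e299) low_min = up_max;
        out.bias = 0.5 * (up_max + low_min);
    }
    out.iterations = it;
    out.converged = conv;
    return out;
}

inline double choose_ll(int n, int k)
{
    if (k < 0 || k > n) return 0.0;
    double r = 1.0;
    for (int i = 1; i <= k; ++i) r = r * (double)(n - k + i) / (double)i;
    return std::floor(r + 0.5);
}

// lexicographic unranking of k-combinations of {0,...,n-1}
void unrank_combination(double rank, int n, int k, std::vector<int>& c)
{
    c.resize(k);
    double r = rank;
    int v = 0;
    for (int i = 0; i < k; ++i) {
        for (;;) {
            const double cnt = choose_ll(n - 1 - v, k - 1 - i);
            if (r < cnt) break;
            r -= cnt;
            ++v;
        }
        c[i] = v++;
    }
}

// advance to the next combination in lexicographic order; false when exhausted
inline bool next_combination(std::vector<int>& c, int n, int k)
{
    int i = k - 1;
    while (i >= 0 && c[i] == n - k + i) --i;
    if (i < 0) return false;
    ++c[i];
    for (int j = i + 1; j < k; ++j) c[j] = c[j - 1] + 1;
    return true;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(NumericMatrix X, IntegerVector y, double cost,
                 double tol, int max_iter)
{
    const int n = X.nrow(), p = X.ncol();
    std::vector<int> yy(n);
    for (int i = 0; i < n; ++i) yy[i] = y[i];

    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
            double s = 0.0;
            for (int d = 0; d < p; ++d) s += X(i, d) * X(j, d);
            K[(size_t)i * n + j] = s;
            K[(size_t)j * n + i] = s;
        }
    }

    SmoFit fit = smo_solve(K, yy, n, cost, tol, max_iter);

    NumericVector dec(n), alpha(n);
    for (int t = 0; t < n; ++t) {
        double s = 0.0;
        for (int i = 0; i < n; ++i)
            s += fit.alpha[i] * (double)yy[i] * K[(size_t)i * n + t];
        dec[t] = s + fit.bias;
        alpha[t] = fit.alpha[t];
    }

    NumericVector w(p);
    for (int d = 0; d < p; ++d) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += fit.alpha[i] * (double)yy[i] * X(i, d);
        w[d] = s;
    }

    return List::create(_["alpha"] = alpha, _["bias"] = fit.bias,
                        _["weights"] = w, _["decision"] = dec,
                        _["iterations"] = fit.iterations,
                        _["converged"] = fit.converged);
}

//' @noRd
// [[Rcpp::export(name = ".count_combinations_stream_cpp")]]
double count_combinations_stream_cpp(int n, int k)
{
    if (k < 1 || k > n) stop("require 1 <= k <= n");
    std::vector<int> c(k);
    for (int i = 0; i < k; ++i) c[i] = i;
    double count = 1.0;
    while (next_combination(c, n, k)) count += 1.0;
    return count;
}

// Exhaustive SVM scoring of all k-combinations of feature columns with
// lexicographic ranks in [start_rank, end_rank). X is samples x features on
// the scale to be modelled (log2 LFQ); each combination's columns are
// z-scored (sd denominator n-1; zero sd -> 1) before fitting.
// Panels with n_correct >= best - keep_slack are retained (at most max_store).
//' @noRd
// [[Rcpp::export(name = ".svm_search_cpp")]]
List svm_search_cpp(NumericMatrix X, IntegerVector y, int k, double cost,
                    double tol, int max_iter, double start_rank,
                    double end_rank, int keep_slack, int max_store)
{
    const int n = X.nrow(), p = X.ncol();
    if (k < 1 || k > p) stop("require 1 <= k <= number of features");
    const double total = choose_ll(p, k);
    if (start_rank < 0 || end_rank > total || start_rank > end_rank)
        stop("invalid rank range");

    std::vector<int> yy(n);
    for (int i = 0; i < n; ++i) yy[i] = y[i];

    std::vector<int> combo;
    unrank_combination(start_rank, p, k, combo);

    std::vector<double> Z((size_t)n * k);          // standardized submatrix, col-major
    std::vector<double> K((size_t)n * n);
    std::vector<int> kept_combo;                   // flattened k-tuples (0-based)
    std::vector<int> kept_correct;
    std::vector<double> kept_margin;               // geometric margin 1/||w||
    int best_correct = -1;
    bool overflow = false;

    double n_tested = 0.0;
    for (double rank = start_rank; rank < end_rank; rank += 1.0) {
        // standardize the k selected columns
        for (int d = 0; d < k; ++d) {
            const int col = combo[d];
            double m = 0.0;
            for (int i = 0; i < n; ++i) m += X(i, col);
            m /= n;
            double ss = 0.0;
            for (int i = 0; i < n; ++i) {
                const double dv = X(i, col) - m;
                ss += dv * dv;
            }
            double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : 1.0;
            if (sd <= 0.0) sd = 1.0;
            for (int i = 0; i < n; ++i)
                Z[(size_t)d * n + i] = (X(i, col) - m) / sd;
        }
        for (int i = 0; i < n; ++i) {
            for (int j = i; j < n; ++j) {
                double s = 0.0;
                for (int d = 0; d < k; ++d)
                    s += Z[(size_t)d * n + i] * Z[(size_t)d * n + j];
                K[(size_t)i * n + j] = s;
                K[(size_t)j * n + i] = s;
            }
        }

        SmoFit fit = smo_solve(K, yy, n, cost, tol, max_iter);

        int correct = 0;
        for (int t = 0; t < n; ++t) {
            double s = 0.0;
            for (int i = 0; i < n; ++i)
                s += fit.alpha[i] * (double)yy[i] * K[(size_t)i * n + t];
            const double dec = s + fit.bias;
            const int pred = (dec >= 0.0) ? 1 : -1;
            if (pred == yy[t]) ++correct;
        }

        if (correct > best_correct) {
            best_correct = correct;
            // prune entries that fell out of the slack band
            size_t w = 0;
            for (size_t r = 0; r < kept_correct.size(); ++r) {
                if (kept_correct[r] >= best_correct - keep_slack) {
                    kept_correct[w] = kept_correct[r];
                    kept_margin[w] = kept_margin[r];
                    for (int d = 0; d < k; ++d)
                        kept_combo[w * k + d] = kept_combo[r * k + d];
                    ++w;
                }
            }
            kept_correct.resize(w);
            kept_margin.resize(w);
            kept_combo.resize(w * (size_t)k);
        }
        if (correct >= best_correct - keep_slack) {
            if ((int)kept_correct.size() < max_store) {
                double wn2 = 0.0;
                for (int d = 0; d < k; ++d) {
                    double wd = 0.0;
                    for (int i = 0; i < n; ++i)
                        wd += fit.alpha[i] * (double)yy[i] * Z[(size_t)d * n + i];
                    wn2 += wd * wd;
                }
                kept_correct.push_back(correct);
                kept_margin.push_back(wn2 > 0.0 ? 1.0 / std::sqrt(wn2) : R_PosInf);
                for (int d = 0; d < k; ++d) kept_combo.push_back(combo[d]);
            } else {
                overflow = true;
            }
        }

        n_tested += 1.0;
        if (rank + 1.0 < end_rank) next_combination(combo, p, k);
        if (((long long)n_tested & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }

    const size_t m = kept_correct.size();
    IntegerMatrix panels((int)m, k);
    IntegerVector correct_v((int)m);
    NumericVector margin_v((int)m);
    for (size_t r = 0; r < m; ++r) {
        correct_v[(int)r] = kept_correct[r];
        margin_v[(int)r] = kept_margin[r];
        for (int d = 0; d < k; ++d) panels((int)r, d) = kept_combo[r * (size_t)k + d] + 1;
    }

    return List::create(_["n_tested"] = n_tested,
                        _["best_correct"] = best_correct,
                        _["panels"] = panels,
                        _["panel_correct"] = correct_v,
                        _["panel_margin"] = margin_v,
                        _["overflow"] = overflow);
}
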