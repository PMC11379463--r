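#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS: argmin_{x >= 0} || A x - b ||_2.
// A is m x n with small n (the number of latent factors), so the repeated
// dense solves on the passive set are cheap. Finite termination is
// guaranteed; maxit is a safety net only.
static vec nnls_lawson_hanson(const mat& A, const vec& b) {
    const uword n = A.n_cols;
    vec x(n, fill::zeros);
    if (n == 0 || A.n_rows == 0) return x;

    std::vector<bool> passive(n, false);
    vec w = A.t() * (b - A * x);
    const double tol = 10.0 * datum::eps * norm(A, 1) *
        static_cast<double>(std::max(A.n_rows, A.n_cols));
    const uword maxit = 3 * n + 30;

    for (uword outer = 0; outer < maxit; ++outer) {
        // pick the most violated KKT multiplier among active (zero) coords
        double wmax = tol;
        sword jmax = -1;
        for (uword j = 0; j < n; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
        }
        if (jmax < 0) break;
        passive[jmax] = true;

        // inner loop: solve on the passive set, back off along the segment
        // towards x while any passive coordinate would go negative
        for (uword inner = 0; inner < maxit; ++inner) {
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
            P.resize(np);

            vec z;
            bool ok = solve(z, A.cols(P), b);
            if (!ok) z = pinv(A.cols(P)) * b;

            if (np > 0 && z.min() > tol) {
                x.zeros();
                x(P) = z;
                break;
            }
            double alpha = datum::inf;
            for (uword k = 0; k < np; ++k) {
                if (z(k) <= tol) {
                    double xi = x(P(k));
                    double a = xi / (xi - z(k) + datum::eps);
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < np; ++k) {
                x(P(k)) += alpha * (z(k) - x(P(k)));
            }
            for (uword j = 0; j < n; ++j) {
                if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
            }
        }
        w = A.t() * (b - A * x);
    }
    // clip numerical dust
    for (uword j = 0; j < n; ++j) if (x(j) < 0) x(j) = 0.0;
    return x;
}

// [[Rcpp::export(name = ".nnls_cpp")]]
arma::vec nnls_cpp(const arma::mat& A, const arma::vec& b) {
    return nnls_lawson_hanson(A, b);
}

static double weighted_cost_cpp(const mat& M, const mat& W, const mat& C,
                                const mat& V) {
    mat R = M - C * V;
    return accu(W % (R % R));
}

// [[Rcpp::export(name = ".wnmf_cost_cpp")]]
double wnmf_cost_cpp(const arma::mat& M, const arma::mat& W,
                     const arma::mat& C, const arma::mat& V) {
    return weighted_cost_cpp(M, W, C, V);
}

// Active-set NNLS on the normal equations (Bro & de Jong's fast NNLS):
// argmin_{x >= 0} x' G x / 2 - x' h with G = A'A, h = A'b. Exact for the
// small K used here; same minimizer as Lawson-Hanson on (A, b).
static vec fnnls(const mat& G, const vec& h) {
    const uword n = G.n_rows;
    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = h;  // gradient -(Gx - h) at x = 0
    const double tol = 10.0 * datum::eps *
        std::max(1.0, G.diag().max()) * static_cast<double>(n);
    const uword maxit = 3 * n + 30;

    for (uword outer = 0; outer < maxit; ++outer) {
        double wmax = tol;
        sword jmax = -1;
        for (uword j = 0; j < n; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
        }
        if (jmax < 0) break;
        passive[jmax] = true;

        for (uword inner = 0; inner < maxit; ++inner) {
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
            P.resize(np);

            vec z;
            bool ok = solve(z, G(P, P), h(P), solve_opts::likely_sympd);
            if (!ok) z = pinv(G(P, P)) * h(P);

            if (np > 0 && z.min() > tol) {
                x.zeros();
                x(P) = z;
                break;
            }
            double alpha = datum::inf;
            for (uword k = 0; k < np; ++k) {
                if (z(k) <= tol) {
                    double xi = x(P(k));
                    double a = xi / (xi - z(k) + datum::eps);
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < np; ++k) {
                x(P(k)) += alpha * (z(k) - x(P(k)));
            }
            for (uword j = 0; j < n; ++j) {
                if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
            }
        }
        w = h - G * x;
    }
    for (uword j = 0; j < n; ++j) if (x(j) < 0) x(j) = 0.0;
    return x;
}

// One half-step: given fixed factors F (r x K) and target columns of X
// (r x s) with weights Wt (r x s), solve each column j of the s outputs as
// an independent weighted NNLS with design F and weights Wt.col(j).
// The per-column Gram matrices F' diag(w_j) F are assembled for every j at
// once from two dense products over the pairwise column products of F.
static mat solve_block(const mat& F, const mat& X, const mat& Wt) {
    const uword K = F.n_cols;
    const uword s = X.n_cols;
    mat out(K, s, fill::zeros);

    const uword npair = K * (K + 1) / 2;
    mat P(F.n_rows, npair);
    uword c = 0;
    for (uword k = 0; k < K; ++k) {
        for (uword l = k; l < K; ++l) {
            P.col(c++) = F.col(k) % F.col(l);
        }
    }
    mat Gall = P.t() * Wt;            // npair x s
    mat Hall = F.t() * (Wt % X);      // K x s

    mat G(K, K);
    for (uword j = 0; j < s; ++j) {
        c = 0;
        for (uword k = 0; k < K; ++k) {
            for (uword l = k; l < K; ++l) {
                G(k, l) = G(l, k) = Gall(c++, j);
            }
        }
        if (G.diag().max() <= 0) continue;  // no covered entries
        out.col(j) = fnnls(G, Hall.col(j));
    }
    return out;
}

// Alternating exact weighted NNLS for M ~ C V under elementwise weights W.
// C0 is the (n_cells x K) initialization; returns C, V and the cost after
// each full iteration. Early stop: relative cost change < tol over `window`
// consecutive iterations.
// [[Rcpp::export(name = ".wnmf_fit_cpp")]]
Rcpp::List wnmf_fit_cpp(const arma::mat& M, const arma::mat& W,
                        const arma::mat& C0, int n_iter, double tol,
                        int window) {
    mat C = C0;
    const uword K = C.n_cols;
    mat V(K, M.n_cols, fill::zeros);
    std::vector<double> trace;
    trace.reserve(n_iter);

    int it = 0;
    for (; it < n_iter; ++it) {
        // V-update: each variant column j is a weighted NNLS with design C
        V = solve_block(C, M, W);
        // C-update: each cell row i is a weighted NNLS with design V'
        C = solve_block(V.t(), M.t(), W.t()).t();
        double e = weighted_cost_cpp(M, W, C, V);
        trace.push_back(e);
        int t = static_cast<int>(trace.size());
        if (window > 0 && t > window) {
            double prev = trace[t - 1 - window];
            double rel = std::abs(prev - trace[t - 1]) /
                std::max(prev, 1e-300);
            if (rel < tol) { ++it; break; }
        }
    }
    return Rcpp::List::create(
        Rcpp::Named("C") = C,
        Rcpp::Named("V") = V,
        Rcpp::Named("cost_trace") = trace,
        Rcpp::Named("n_iter") = static_cast<int>(trace.size()));
}
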