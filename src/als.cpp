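// Alternating least squares core for the constrained bilinear model
//   logG (m x n)  =  CS (m x p, fixed zero pattern)  *  logTFA (p x n).
// Each half-step is an exact least-squares minimizer, so the objective
// (squared Frobenius residual) is non-increasing at every half-step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// inits: p x n x R cube of initial logTFA draws, one slice per restart.
// Returns the best restart by final objective (ties -> first restart).
// A rank-deficient per-gene sub-problem aborts with "RANKDEF:<i>" (the
// 1-based gene row); a rank-deficient TFA step with "RANKDEFTFA".
// [[Rcpp::export]]
Rcpp::List alsFitCpp(const arma::mat& logG, const arma::mat& mask,
                     const arma::cube& inits, int maxIter, double tol) {
    const uword m = logG.n_rows, n = logG.n_cols, p = mask.n_cols;
    if (mask.n_rows != m || inits.n_rows != p || inits.n_cols != n)
        Rcpp::stop("dimension mismatch");
    const uword R = inits.n_slices;

    std::vector<uvec> regs(m);
    for (uword i = 0; i < m; ++i)
        regs[i] = find(mask.row(i) != 0);

    double bestObj = datum::inf;
    mat bestCS, bestT;
    std::vector<double> bestTrace;
    int bestIter = 0, bestRestart = 0;
    bool bestConv = false;

    for (uword r = 0; r < R; ++r) {
        mat T = inits.slice(r);
        mat CS(m, p, fill::zeros);
        std::vector<double> trace;
        trace.reserve(2 * (size_t)maxIter);
        double prev = datum::inf;
        bool conv = false;
        int iter = 0;

        for (iter = 1; iter <= maxIter; ++iter) {
            // CS-step: per-gene OLS restricted to its regulators
            for (uword i = 0; i < m; ++i) {
                const uvec& ri = regs[i];
                if (ri.n_elem == 0) continue;
                mat A = T.rows(ri).t();              // n x k_i
                vec ci;
                bool ok = solve(ci, A, logG.row(i).t(),
                                solve_opts::no_approx);
                if (!ok)
                    Rcpp::stop("RANKDEF:" + std::to_string(i + 1));
                for (uword k = 0; k < ri.n_elem; ++k)
                    CS(i, ri[k]) = ci[k];
            }
            double objA = accu(square(logG - CS * T));
            trace.push_back(objA);

            // TFA-step: per-condition OLS over all p activities
            mat Tnew;
            bool ok = solve(Tnew, CS, logG, solve_opts::no_approx);
            if (!ok) Rcpp::stop("RANKDEFTFA");
            T = Tnew;
            double objB = accu(square(logG - CS * T));
            trace.push_back(objB);

            if (std::isfinite(prev) &&
                (prev - objB) <= tol * std::max(prev, 1e-300)) {
                conv = true;
                break;
            }
            prev = objB;
        }
        if (iter > maxIter) iter = maxIter;
        double objFinal = trace.back();
        if (objFinal < bestObj) {
            bestObj = objFinal;
            bestCS = CS;
            bestT = T;
            bestTrace = trace;
            bestIter = iter;
            bestConv = conv;
            bestRestart = (int)r + 1;
        }
    }

    return Rcpp::List::create(
        Rcpp::Named("cs") = bestCS,
        Rcpp::Named("logTfa") = bestT,
        Rcpp::Named("objective") = bestObj,
        Rcpp::Named("trace") = bestTrace,
        Rcpp::Named("iterations") = bestIter,
        Rcpp::Named("converged") = bestConv,
        Rcpp::Named("restartIndex") = bestRestart);
}
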