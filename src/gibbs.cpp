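// Gibbs sampler for the four-component normal-mixture GWAS model.
//
// Model: y = W a + sum_j x_j b_j + e,  e ~ N(0, s2e I)
//   b_j | class k ~ N(0, gamma_k * s2g), gamma = (0, 1e-4, 1e-3, 1e-2)
//   class ~ Categorical(pi), pi ~ Dirichlet(alpha)
//   s2g, s2e ~ scaled inverse chi-square conditionals
// Residual is kept up to date with the subtract/add trick, O(n m) per
// iteration.  Uses R's RNG so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".bayesr_gibbs")]]
List bayesr_gibbs(const arma::mat& X,      // n x m centered genotypes
                  const arma::vec& y,
                  const arma::mat& W,      // n x p fixed effects (incl. intercept)
                  const arma::vec& gamma,  // K variance coefficients, gamma[0] == 0
                  const int niter, const int burnin, const int thin,
                  const arma::vec& dir_alpha,
                  const double nu_g, const double s_g,
                  const double nu_e, const double s_e) {
    const int n = X.n_rows, m = X.n_cols, p = W.n_cols, K = gamma.n_elem;

    // BLAS-backed aliases of the genotype columns (no copies)
    std::vector<arma::vec> xcol;
    xcol.reserve(m);
    for (int j = 0; j < m; ++j)
        xcol.emplace_back(const_cast<double*>(X.colptr(j)), n, false, true);

    // single-precision copy for the per-variant dot products: the sampler
    // is memory-bound on streaming X every iteration, and float traffic
    // halves it; residuals and all draws stay in double precision
    arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
    std::vector<arma::fvec> fcol;
    fcol.reserve(m);
    for (int j = 0; j < m; ++j)
        fcol.emplace_back(Xf.colptr(j), n, false, true);

    arma::vec xx(m), ww(p);
    for (int j = 0; j < m; ++j) xx[j] = arma::dot(xcol[j], xcol[j]);
    for (int l = 0; l < p; ++l) ww[l] = arma::dot(W.col(l), W.col(l));

    arma::vec beta(m, arma::fill::zeros), alpha(p, arma::fill::zeros);
    arma::ivec cls(m, arma::fill::zeros);  // current class of each variant
    arma::vec pi(K);
    pi.fill(1.0 / K);
    const double vy = arma::var(y);
    double s2e = (0.5 * vy > 0) ? 0.5 * vy : 1.0;
    double s2g = s2e;
    arma::vec r = y - W * alpha;

    arma::vec beta_sum(m, arma::fill::zeros);
    arma::mat cls_sum(m, K, arma::fill::zeros);
    arma::vec pi_sum(K, arma::fill::zeros), alpha_sum(p, arma::fill::zeros);
    double s2g_sum = 0.0, s2e_sum = 0.0;
    std::vector<double> s2g_trace;
    int nkept = 0;

    std::vector<int> order(m);
    for (int j = 0; j < m; ++j) order[j] = j;
    arma::vec logL(K), prob(K);
    arma::vec counts(K);

    arma::fvec rf(n);

    for (int it = 0; it < niter; ++it) {
        const bool keep = (it >= burnin) && ((it - burnin) % thin == 0);

        // fixed effects, flat prior
        for (int l = 0; l < p; ++l) {
            if (ww[l] <= 0) continue;
            r += W.col(l) * alpha[l];
            const double rhs = arma::dot(W.col(l), r);
            alpha[l] = rhs / ww[l] + std::sqrt(s2e / ww[l]) * norm_rand();
            r -= W.col(l) * alpha[l];
        }

        // random variant order each iteration (Fisher-Yates on R's RNG)
        for (int j = m - 1; j > 0; --j) {
            int k = (int)std::floor(unif_rand() * (j + 1));
            if (k > j) k = j;
            std::swap(order[j], order[k]);
        }

        // refresh the float residual from the exact one each iteration
        rf = arma::conv_to<arma::fvec>::from(r);

        counts.zeros();
        for (int idx = 0; idx < m; ++idx) {
            const int j = order[idx];
            if (xx[j] <= 0) {  // monomorphic after centering: point mass
                beta[j] = 0.0; cls[j] = 0; counts[0] += 1.0;
                if (keep) cls_sum(j, 0) += 1.0;
                continue;
            }
            // rhs for the model without variant j: dot against the full
            // residual, adding back j's own contribution analytically
            const double rhs = (double)arma::dot(fcol[j], rf)
                + xx[j] * beta[j];
            // class weights: pi_k * sqrt(s2e/den_k) * exp(exponent_k),
            // computed on the exponent scale to avoid overflow
            double emax = 0.0;  // class 1 has exponent 0
            for (int k = 0; k < K; ++k) {
                const double v = gamma[k] * s2g;
                if (v <= 0) {
                    logL[k] = 0.0;   // exponent
                    prob[k] = pi[k]; // scale factor
                } else {
                    const double den = v * xx[j] + s2e;
                    logL[k] = 0.5 * rhs * rhs * v / (s2e * den);
                    prob[k] = pi[k] * std::sqrt(s2e / den);
                }
                if (logL[k] > emax) emax = logL[k];
            }
            double tot = 0.0;
            for (int k = 0; k < K; ++k) {
                prob[k] *= std::exp(logL[k] - emax);
                tot += prob[k];
            }
            const double u = unif_rand() * tot;
            int knew = K - 1;
            double acc = 0.0;
            for (int k = 0; k < K; ++k) {
                acc += prob[k];
                if (u <= acc) { knew = k; break; }
            }
            cls[j] = knew;
            counts[knew] += 1.0;
            const double v = gamma[knew] * s2g;
            double bj = 0.0;
            if (v > 0) {
                const double prec = xx[j] + s2e / v;
                bj = rhs / prec + std::sqrt(s2e / prec) * norm_rand();
            }
            const double delta = beta[j] - bj;  // r tracks y - Wa - Xb
            if (delta != 0.0) {
                r += xcol[j] * delta;
                rf += fcol[j] * (float)delta;
            }
            beta[j] = bj;
            if (keep) cls_sum(j, knew) += 1.0;
        }

        // pi ~ Dirichlet(alpha + class counts)
        double gtot = 0.0;
        for (int k = 0; k < K; ++k) {
            pi[k] = R::rgamma(dir_alpha[k] + counts[k], 1.0);
            gtot += pi[k];
        }
        pi /= gtot;

        // genetic variance: beta_j | class k ~ N(0, gamma_k s2g)
        double ssb = 0.0;
        int q = 0;
        for (int j = 0; j < m; ++j) {
            if (beta[j] != 0.0) {
                ssb += beta[j] * beta[j] / gamma[cls[j]];
                ++q;
            }
        }
        s2g = (ssb + nu_g * s_g) / R::rchisq(nu_g + q);

        // residual variance
        const double sse = arma::dot(r, r);
        s2e = (sse + nu_e * s_e) / R::rchisq(nu_e + n);

        if (keep) {
            beta_sum += beta;
            pi_sum += pi;
            alpha_sum += alpha;
            s2g_sum += s2g;
            s2e_sum += s2e;
            s2g_trace.push_back(s2g);
            ++nkept;
        }
    }

    const double dk = std::max(nkept, 1);
    return List::create(
        _["beta_mean"] = arma::vec(beta_sum / dk),
        _["class_prob"] = arma::mat(cls_sum / dk),
        _["pi_mean"] = arma::vec(pi_sum / dk),
        _["alpha_mean"] = arma::vec(alpha_sum / dk),
        _["varG_mean"] = s2g_sum / dk,
        _["varE_mean"] = s2e_sum / dk,
        _["varG_trace"] = s2g_trace,
        _["n_kept"] = nkept);
}
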