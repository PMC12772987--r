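// Fast path for the event-count regressor: fused forward/backward training
// step, inference prediction, and batch-normalization statistics, all on
// the same (batch x time, channel) column-major layout the R reference
// implementation uses. Convolutions are im2col + GEMM; dropout draws from
// R's RNG so a single seed reproduces training exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

struct Block {
    arma::mat W;
    arma::rowvec b, gamma, beta, rmean, rvar;
};

static std::vector<Block> readBlocks(const List& params) {
    List bl = params["blocks"];
    std::vector<Block> out(bl.size());
    for (int i = 0; i < bl.size(); ++i) {
        List p = bl[i];
        out[i].W = as<arma::mat>(p["W"]);
        out[i].b = as<arma::rowvec>(p["b"]);
        out[i].gamma = as<arma::rowvec>(p["gamma"]);
        out[i].beta = as<arma::rowvec>(p["beta"]);
        out[i].rmean = as<arma::rowvec>(p["rmean"]);
        out[i].rvar = as<arma::rowvec>(p["rvar"]);
    }
    return out;
}

// A: (N*L, Cin) -> (N*L, K*Cin), same-padding, stride 1, tap j reads input
// position l + j - pad.
static arma::mat im2col(const arma::mat& A, int N, int L, int K) {
    int Cin = A.n_cols;
    int pad = (K - 1) / 2;
    arma::mat M(N * L, K * Cin, arma::fill::zeros);
    for (int j = 0; j < K; ++j) {
        int dt = j - pad;
        int l0 = std::max(0, -dt), l1 = std::min(L, L - dt);
        if (l1 <= l0) continue;
        M.submat(N * l0, j * Cin, N * l1 - 1, (j + 1) * Cin - 1) =
            A.rows(N * (l0 + dt), N * (l1 + dt) - 1);
    }
    return M;
}

static arma::mat col2im(const arma::mat& dM, int N, int L, int K, int Cin) {
    int pad = (K - 1) / 2;
    arma::mat dA(N * L, Cin, arma::fill::zeros);
    for (int j = 0; j < K; ++j) {
        int dt = j - pad;
        int l0 = std::max(0, -dt), l1 = std::min(L, L - dt);
        if (l1 <= l0) continue;
        dA.rows(N * (l0 + dt), N * (l1 + dt) - 1) +=
            dM.submat(N * l0, j * Cin, N * l1 - 1, (j + 1) * Cin - 1);
    }
    return dA;
}

// Max pooling; ties keep the earliest sample (strict > to update).
static void poolFwd(const arma::mat& A, int N, int L, int pool,
                    arma::mat& Y, arma::Mat<int>& argm) {
    int Lo = L / pool, C = A.n_cols;
    Y.set_size(N * Lo, C);
    argm.set_size(N * Lo, C);
    for (int c = 0; c < C; ++c) {
        const double* a = A.colptr(c);
        double* y = Y.colptr(c);
        int* g = argm.colptr(c);
        for (int lo = 0; lo < Lo; ++lo) {
            for (int n = 0; n < N; ++n) {
                double best = a[n + (size_t)N * (lo * pool)];
                int bj = 0;
                for (int j = 1; j < pool; ++j) {
                    double v = a[n + (size_t)N * (lo * pool + j)];
                    if (v > best) { best = v; bj = j; }
                }
                y[n + (size_t)N * lo] = best;
                g[n + (size_t)N * lo] = bj;
            }
        }
    }
}

static arma::mat poolBwd(const arma::mat& dY, const arma::Mat<int>& argm,
                         int N, int Lin, int pool) {
    int Lo = dY.n_rows / N, C = dY.n_cols;
    arma::mat dA(N * Lin, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
        const double* dy = dY.colptr(c);
        const int* g = argm.colptr(c);
        double* da = dA.colptr(c);
        for (int lo = 0; lo < Lo; ++lo) {
            for (int n = 0; n < N; ++n) {
                size_t i = n + (size_t)N * lo;
                da[n + (size_t)N * (lo * pool + g[i])] = dy[i];
            }
        }
    }
    return dA;
}

// One fused forward + backward pass over a minibatch, returning gradients,
// the summed Huber loss, and the batch normalization statistics.
// [[Rcpp::export]]
List cppTrainStep(const List& params, const arma::mat& Xin,
                  const arma::vec& y, double delta, int kernel, int pool,
                  double rdrop) {
    std::vector<Block> B = readBlocks(params);
    int nB = B.size();
    int N = Xin.n_rows, L0 = Xin.n_cols;

    arma::mat Acur(Xin.memptr(), (size_t)N * L0, 1);
    int L = L0;

    std::vector<arma::mat> cM(nB), cXhat(nB), cRelu(nB), cDrop(nB);
    std::vector<arma::rowvec> cSdv(nB), bMean(nB), bVar(nB);
    std::vector<arma::Mat<int>> cArg(nB);
    std::vector<int> cL(nB);

    for (int b = 0; b < nB; ++b) {
        arma::mat M = im2col(Acur, N, L, kernel);
        arma::mat Z = M * B[b].W;
        Z.each_row() += B[b].b;
        double m = (double)N * L;
        arma::rowvec mu = arma::mean(Z, 0);
        Z.each_row() -= mu;
        arma::rowvec var = arma::sum(arma::square(Z), 0) / m;
        arma::rowvec sdv = arma::sqrt(var + BN_EPS);
        Z.each_row() /= sdv;                 // Z is now xhat
        arma::mat Y = Z;
        Y.each_row() %= B[b].gamma;
        Y.each_row() += B[b].beta;
        Y.transform([](double v) { return v > 0 ? v : 0.0; });

        cM[b] = std::move(M);
        cXhat[b] = std::move(Z);
        cSdv[b] = sdv;
        bMean[b] = mu;
        bVar[b] = var;
        cL[b] = L;

        arma::mat P;
        arma::Mat<int> arg;
        poolFwd(Y, N, L, pool, P, arg);
        cRelu[b] = std::move(Y);
        cArg[b] = std::move(arg);
        if (rdrop > 0) {
            arma::mat mask(P.n_rows, P.n_cols);
            double* mp = mask.memptr();
            double scale = 1.0 / (1.0 - rdrop);
            for (size_t i = 0; i < mask.n_elem; ++i) {
                mp[i] = (unif_rand() >= rdrop) ? scale : 0.0;
            }
            P %= mask;
            cDrop[b] = std::move(mask);
        }
        Acur = std::move(P);
        L = L / pool;
    }

    List head = params["head"];
    arma::vec w = as<arma::vec>(head["w"]);
    double hb = as<double>(head["b"]);
    int D = Acur.n_elem / N;
    arma::mat Xf(Acur.memptr(), N, D, false, true);
    arma::vec pred = Xf * w + hb;

    double loss = 0.0;
    arma::vec dpred(N);
    for (int i = 0; i < N; ++i) {
        double r = pred[i] - y[i], a = std::fabs(r);
        loss += (a <= delta) ? 0.5 * r * r : delta * (a - 0.5 * delta);
        dpred[i] = ((a <= delta) ? r : delta * ((r > 0) - (r < 0))) / N;
    }
    if (!std::isfinite(loss)) {
        return List::create(_["loss"] = loss);
    }

    arma::vec gw = Xf.t() * dpred;
    double gb = arma::accu(dpred);
    arma::mat dAcur = dpred * w.t();     // (N, D)
    dAcur.reshape((size_t)N * L, D / std::max(L, 1));

    List gblocks(nB);
    for (int b = nB - 1; b >= 0; --b) {
        if (cDrop[b].n_elem > 0) dAcur %= cDrop[b];
        arma::mat dR = poolBwd(dAcur, cArg[b], N, cL[b], pool);
        // ReLU backward
        {
            const double* rp = cRelu[b].memptr();
            double* dp = dR.memptr();
            for (size_t i = 0; i < dR.n_elem; ++i) {
                if (rp[i] <= 0) dp[i] = 0;
            }
        }
        double m = (double)dR.n_rows;
        arma::rowvec dgamma = arma::sum(dR % cXhat[b], 0);
        arma::rowvec dbeta = arma::sum(dR, 0);
        dR.each_row() %= B[b].gamma;      // dxhat
        arma::rowvec mean1 = arma::mean(dR, 0);
        arma::rowvec mean2 = arma::sum(dR % cXhat[b], 0) / m;
        dR.each_row() -= mean1;
        dR -= cXhat[b].each_row() % mean2;
        dR.each_row() /= cSdv[b];
        // conv backward
        int Cin = B[b].W.n_rows / kernel;
        arma::mat gW = cM[b].t() * dR;
        arma::rowvec gbias = arma::sum(dR, 0);
        arma::mat dM = dR * B[b].W.t();
        dAcur = col2im(dM, N, cL[b], kernel, Cin);

        gblocks[b] = List::create(
            _["W"] = wrap(gW),
            _["b"] = NumericVector(gbias.begin(), gbias.end()),
            _["gamma"] = NumericVector(dgamma.begin(), dgamma.end()),
            _["beta"] = NumericVector(dbeta.begin(), dbeta.end()));
    }

    List stats(nB);
    for (int b = 0; b < nB; ++b) {
        stats[b] = List::create(
            _["mean"] = NumericVector(bMean[b].begin(), bMean[b].end()),
            _["var"] = NumericVector(bVar[b].begin(), bVar[b].end()));
    }
    return List::create(
        _["loss"] = loss,
        _["grads"] = List::create(
            _["blocks"] = gblocks,
            _["head"] = List::create(
                _["w"] = NumericVector(gw.begin(), gw.end()),
                _["b"] = gb)),
        _["stats"] = stats);
}

// Inference forward pass: running batch-norm statistics, no dropout.
// [[Rcpp::export]]
arma::vec cppPredict(const List& params, const arma::mat& Xin, int kernel,
                     int pool) {
    std::vector<Block> B = readBlocks(params);
    int N = Xin.n_rows, L = Xin.n_cols;
    arma::mat Acur(Xin.memptr(), (size_t)N * L, 1);
    for (size_t b = 0; b < B.size(); ++b) {
        arma::mat M = im2col(Acur, N, L, kernel);
        arma::mat Z = M * B[b].W;
        arma::rowvec scale = B[b].gamma / arma::sqrt(B[b].rvar + BN_EPS);
        arma::rowvec shift = B[b].beta + (B[b].b - B[b].rmean) % scale;
        Z.each_row() %= scale;
        Z.each_row() += shift;
        Z.transform([](double v) { return v > 0 ? v : 0.0; });
        arma::mat P;
        arma::Mat<int> arg;
        poolFwd(Z, N, L, pool, P, arg);
        Acur = std::move(P);
        L = L / pool;
    }
    List head = params["head"];
    arma::vec w = as<arma::vec>(head["w"]);
    double hb = as<double>(head["b"]);
    int D = Acur.n_elem / N;
    arma::mat Xf(Acur.memptr(), N, D, false, true);
    return Xf * w + hb;
}

// Batch-normalization statistics of one chunk under training-mode
// normalization with dropout off (used for the per-epoch refresh of the
// running statistics over the whole training set).
// [[Rcpp::export]]
List cppBatchStats(const List& params, const arma::mat& Xin, int kernel,
                   int pool) {
    std::vector<Block> B = readBlocks(params);
    int nB = B.size();
    int N = Xin.n_rows, L = Xin.n_cols;
    arma::mat Acur(Xin.memptr(), (size_t)N * L, 1);
    List stats(nB);
    for (int b = 0; b < nB; ++b) {
        arma::mat M = im2col(Acur, N, L, kernel);
        arma::mat Z = M * B[b].W;
        Z.each_row() += B[b].b;
        double m = (double)N * L;
        arma::rowvec mu = arma::mean(Z, 0);
        Z.each_row() -= mu;
        arma::rowvec var = arma::sum(arma::square(Z), 0) / m;
        stats[b] = List::create(
            _["mean"] = NumericVector(mu.begin(), mu.end()),
            _["var"] = NumericVector(var.begin(), var.end()));
        arma::rowvec sdv = arma::sqrt(var + BN_EPS);
        Z.each_row() /= sdv;
        Z.each_row() %= B[b].gamma;
        Z.each_row() += B[b].beta;
        Z.transform([](double v) { return v > 0 ? v : 0.0; });
        arma::mat P;
        arma::Mat<int> arg;
        poolFwd(Z, N, L, pool, P, arg);
        Acur = std::move(P);
        L = L / pool;
    }
    return stats;
}
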