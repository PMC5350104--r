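// Hot loop for stochastic-gradient training of the two-stage locally
// recurrent network: per epoch, forward over the 5-bin sequence, exact
// backpropagation through time, one SGD step. Static inputs only (the
// training stimuli are static textures); probing with moving stimuli is
// done from R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigm(const arma::vec &x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export]]
List cpp_rfam_sgd(List params, const arma::mat &X, const arma::mat &targets,
                  const arma::uvec &order, double lr, double clip,
                  const arma::uvec &probe_idx, int trace_every,
                  double momentum = 0.0, double weight_decay = 0.0,
                  int n_steps = 5) {
  arma::mat W1 = params["w_in"], R1 = params["w_h1h1"], W2 = params["w_h1h2"],
            R2 = params["w_h2h2"], Wo = params["w_out"];
  arma::vec b1 = params["b1"], b2 = params["b2"], bo = params["b_out"];
  const int n1 = W1.n_rows, n2 = W2.n_rows, no = Wo.n_rows;
  const arma::uword n_epochs = order.n_elem;

  arma::mat h1(n1, n_steps + 1), h2(n2, n_steps + 1), oo(no, n_steps);
  arma::mat dpre1(n1, n_steps), dpre2(n2, n_steps), dout(no, n_steps);

  std::vector<double> trace_err;
  std::vector<double> trace_epoch;

  // momentum buffers
  arma::mat vWo(arma::size(Wo), arma::fill::zeros),
      vW2(arma::size(W2), arma::fill::zeros),
      vR2(arma::size(R2), arma::fill::zeros),
      vW1(arma::size(W1), arma::fill::zeros),
      vR1(arma::size(R1), arma::fill::zeros);
  arma::vec vbo(bo.n_elem, arma::fill::zeros), vb2(b2.n_elem, arma::fill::zeros),
      vb1(b1.n_elem, arma::fill::zeros);

  auto probe_error = [&](void) -> double {
    double tot = 0.0;
    for (arma::uword pi = 0; pi < probe_idx.n_elem; ++pi) {
      arma::uword p = probe_idx[pi];
      arma::vec s = X.row(p).t();
      arma::mat tgt = arma::reshape(targets.row(p).t(), no, n_steps);
      arma::vec ws = W1 * s + b1;
      arma::vec h1p(n1, arma::fill::zeros), h2p(n2, arma::fill::zeros);
      for (int t = 0; t < n_steps; ++t) {
        h1p = sigm(ws + R1 * h1p);
        h2p = sigm(W2 * h1p + R2 * h2p + b2);
        arma::vec o = sigm(Wo * h2p + bo);
        tot += arma::accu(arma::square(o - tgt.col(t)));
      }
    }
    return tot / std::max<arma::uword>(1, probe_idx.n_elem);
  };

  if (trace_every > 0 && probe_idx.n_elem > 0) {
    trace_epoch.push_back(0.0);
    trace_err.push_back(probe_error());
  }

  for (arma::uword e = 0; e < n_epochs; ++e) {
    arma::uword p = order[e];
    arma::vec s = X.row(p).t();
    arma::mat tgt = arma::reshape(targets.row(p).t(), no, n_steps);

    // forward, zero initial recurrent state
    h1.col(0).zeros();
    h2.col(0).zeros();
    arma::vec ws = W1 * s + b1;
    for (int t = 0; t < n_steps; ++t) {
      h1.col(t + 1) = sigm(ws + R1 * h1.col(t));
      h2.col(t + 1) = sigm(W2 * h1.col(t + 1) + R2 * h2.col(t) + b2);
      oo.col(t) = sigm(Wo * h2.col(t + 1) + bo);
    }

    // backward through time: summed squared error over steps
    arma::vec carry2(n2, arma::fill::zeros), carry1(n1, arma::fill::zeros);
    for (int t = n_steps - 1; t >= 0; --t) {
      arma::vec o = oo.col(t);
      dout.col(t) = 2.0 * (o - tgt.col(t)) % o % (1.0 - o);
      arma::vec g2 = Wo.t() * dout.col(t) + carry2;
      dpre2.col(t) = g2 % h2.col(t + 1) % (1.0 - h2.col(t + 1));
      carry2 = R2.t() * dpre2.col(t);
      arma::vec g1 = W2.t() * dpre2.col(t) + carry1;
      dpre1.col(t) = g1 % h1.col(t + 1) % (1.0 - h1.col(t + 1));
      carry1 = R1.t() * dpre1.col(t);
    }

    arma::mat gWo = dout * h2.cols(1, n_steps).t();
    arma::vec gbo = arma::sum(dout, 1);
    arma::mat gW2 = dpre2 * h1.cols(1, n_steps).t();
    arma::mat gR2 = dpre2 * h2.cols(0, n_steps - 1).t();
    arma::vec gb2 = arma::sum(dpre2, 1);
    arma::mat gW1 = arma::sum(dpre1, 1) * s.t();
    arma::mat gR1 = dpre1 * h1.cols(0, n_steps - 1).t();
    arma::vec gb1 = arma::sum(dpre1, 1);

    if (clip > 0) {
      double nrm = std::sqrt(
          arma::accu(arma::square(gWo)) + arma::accu(arma::square(gbo)) +
          arma::accu(arma::square(gW2)) + arma::accu(arma::square(gR2)) +
          arma::accu(arma::square(gb2)) + arma::accu(arma::square(gW1)) +
          arma::accu(arma::square(gR1)) + arma::accu(arma::square(gb1)));
      if (nrm > clip) {
        double sc = clip / nrm;
        gWo *= sc; gbo *= sc; gW2 *= sc; gR2 *= sc; gb2 *= sc;
        gW1 *= sc; gR1 *= sc; gb1 *= sc;
      }
    }

    if (weight_decay > 0) {   // L2 penalty on weights (not biases)
      gWo += weight_decay * Wo;
      gW2 += weight_decay * W2;
      gR2 += weight_decay * R2;
      gW1 += weight_decay * W1;
      gR1 += weight_decay * R1;
    }

    if (momentum > 0) {
      vWo = momentum * vWo + lr * gWo; Wo -= vWo;
      vbo = momentum * vbo + lr * gbo; bo -= vbo;
      vW2 = momentum * vW2 + lr * gW2; W2 -= vW2;
      vR2 = momentum * vR2 + lr * gR2; R2 -= vR2;
      vb2 = momentum * vb2 + lr * gb2; b2 -= vb2;
      vW1 = momentum * vW1 + lr * gW1; W1 -= vW1;
      vR1 = momentum * vR1 + lr * gR1; R1 -= vR1;
      vb1 = momentum * vb1 + lr * gb1; b1 -= vb1;
    } else {
      Wo -= lr * gWo; bo -= lr * gbo;
      W2 -= lr * gW2; R2 -= lr * gR2; b2 -= lr * gb2;
      W1 -= lr * gW1; R1 -= lr * gR1; b1 -= lr * gb1;
    }

    if (!Wo.is_finite() || !W1.is_finite()) {
      stop("training diverged (non-finite weights) at epoch %d", (int)e + 1);
    }

    if (trace_every > 0 && probe_idx.n_elem > 0 &&
        ((e + 1) % (arma::uword)trace_every == 0)) {
      trace_epoch.push_back((double)(e + 1));
      trace_err.push_back(probe_error());
    }
  }

  return List::create(
      _["w_in"] = W1, _["w_h1h1"] = R1, _["b1"] = b1, _["w_h1h2"] = W2,
      _["w_h2h2"] = R2, _["b2"] = b2, _["w_out"] = Wo, _["b_out"] = bo,
      _["trace_epoch"] = trace_epoch, _["trace_error"] = trace_err);
}
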