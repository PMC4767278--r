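// Bulk sigmoid evaluation, isolated in its own translation unit so the
// vectorized math library can be used for the exp-heavy inner loop (see
// Makevars). Accuracy of the vector exp is within a few ulp of libm, far
// inside the integrator's numerical tolerance.
#include <cmath>

extern "C" void wc_sigmoid_batch(int n, const double *x, double *out,
                                 double gain, double offset) {
  for (int i = 0; i < n; ++i) {
    double a = gain * (x[i] - offset);
    if (a > 500.0) a = 500.0;
    if (a < -500.0) a = -500.0;
    out[i] = 1.0 / (1.0 + std::exp(-a));
  }
}
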